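# Synthetic-data generators with known planted structure: two-condition bulk
# cohorts (planted fold-changes and pair correlations), infiltration
# fractions, and negative-binomial single-cell counts with planted
# communication edges. Every generator requires an explicit seed.

#' Construct a bulk-cohort simulation specification
#'
#' Describes a two-condition (normal/cancer) expression cohort. Marginals are
#' log-normal abundances by default (mimicking normalized RNA-seq estimates)
#' or negative-binomial counts. Pair correlations are planted through a
#' Gaussian copula: the latent bivariate-normal correlation r is chosen so
#' that the normal-score Spearman (6/pi) * asin(r/2) equals the target, and
#' each margin is mapped through its quantile function, so the target Spearman
#' holds for any marginal choice.
#'
#' @param genes Character vector of gene symbols.
#' @param n_normal,n_cancer Sample counts per condition (each >= 2).
#' @param meanlog,sdlog Log-normal baseline parameters, recycled over genes.
#' @param nb_mu,nb_size Negative-binomial baseline parameters, recycled.
#' @param marginal `"lognormal"` (default) or `"nb"`.
#' @param planted_de Named numeric vector: gene -> log2 fold-change in cancer.
#' @param planted_corr Data frame with columns `ligand`, `receptor`,
#'   `rho_normal`, `rho_cancer` (target Spearman per condition, |rho| <= 0.95).
#'   Genes may appear in at most one planted pair: joint planting of
#'   correlations sharing a gene is not representable by independent
#'   bivariate copulas and is rejected.
#' @param seed Integer RNG seed (mandatory).
#' @return A `bulk_cohort_spec`.
#' @export
bulk_cohort_spec <- function(genes, n_normal, n_cancer,
                             meanlog = log(100), sdlog = 0.5,
                             nb_mu = 100, nb_size = 10,
                             marginal = c("lognormal", "nb"),
                             planted_de = NULL, planted_corr = NULL,
                             seed) {
  marginal <- match.arg(marginal)
  if (missing(seed)) stop("a simulation spec requires an explicit 'seed'", call. = FALSE)
  assert_scalar_number(seed, "seed")
  genes <- toupper(as.character(genes))
  if (anyDuplicated(genes)) stop("duplicate gene symbols in 'genes'", call. = FALSE)
  if (n_normal < 2 || n_cancer < 2)
    stop("need at least 2 samples per condition", call. = FALSE)
  if (!is.null(planted_de)) {
    if (is.null(names(planted_de)) || any(!nzchar(names(planted_de))))
      stop("'planted_de' must be a named numeric vector", call. = FALSE)
    names(planted_de) <- toupper(names(planted_de))
    missing_de <- setdiff(names(planted_de), genes)
    if (length(missing_de))
      stop("planted DE genes absent from gene list: ",
           paste(missing_de, collapse = ", "), call. = FALSE)
  }
  if (!is.null(planted_corr)) {
    need <- c("ligand", "receptor", "rho_normal", "rho_cancer")
    if (!all(need %in% names(planted_corr)))
      stop("'planted_corr' needs columns ", paste(need, collapse = ", "), call. = FALSE)
    planted_corr$ligand <- toupper(planted_corr$ligand)
    planted_corr$receptor <- toupper(planted_corr$receptor)
    used <- c(planted_corr$ligand, planted_corr$receptor)
    if (anyDuplicated(used))
      stop("a gene appears in more than one planted pair; joint planting is not supported",
           call. = FALSE)
    missing_g <- setdiff(used, genes)
    if (length(missing_g))
      stop("planted pair genes absent from gene list: ",
           paste(missing_g, collapse = ", "), call. = FALSE)
    rhos <- c(planted_corr$rho_normal, planted_corr$rho_cancer)
    if (any(!is.finite(rhos)) || any(abs(rhos) > 0.95))
      stop("target Spearman correlations must be finite with |rho| <= 0.95", call. = FALSE)
  }
  structure(
    list(genes = genes, n_normal = as.integer(n_normal),
         n_cancer = as.integer(n_cancer),
         meanlog = rep_len(meanlog, length(genes)),
         sdlog = rep_len(sdlog, length(genes)),
         nb_mu = rep_len(nb_mu, length(genes)),
         nb_size = rep_len(nb_size, length(genes)),
         marginal = marginal, planted_de = planted_de,
         planted_corr = planted_corr, seed = as.integer(seed)),
    class = "bulk_cohort_spec"
  )
}

#' Construct a bulk cohort container
#'
#' @param expr Numeric genes x samples matrix, non-negative, no missing values.
#' @param condition Character/factor per sample, values `"normal"`/`"cancer"`;
#'   both classes must be present.
#' @param infiltration Optional per-sample infiltration fraction table (see
#'   [simulate_infiltration()]).
#' @return A `bulk_cohort`.
#' @export
bulk_cohort <- function(expr, condition, infiltration = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("'expr' needs gene rownames and sample colnames", call. = FALSE)
  if (anyNA(expr) || any(!is.finite(expr)))
    stop("'expr' contains missing or non-finite values", call. = FALSE)
  if (any(expr < 0)) stop("'expr' contains negative values", call. = FALSE)
  condition <- as.character(condition)
  if (length(condition) != ncol(expr))
    stop("'condition' length must equal the number of samples", call. = FALSE)
  if (!all(condition %in% c("normal", "cancer")))
    stop("'condition' values must be 'normal' or 'cancer'", call. = FALSE)
  if (length(unique(condition)) < 2L)
    stop("both conditions must be present", call. = FALSE)
  structure(list(expr = expr, condition = condition,
                 infiltration = infiltration),
            class = "bulk_cohort")
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat(sprintf("bulk_cohort: %d genes x %d samples (%d normal, %d cancer)\n",
              nrow(x$expr), ncol(x$expr),
              sum(x$condition == "normal"), sum(x$condition == "cancer")))
  invisible(x)
}

# Latent bivariate-normal correlation achieving a target (population)
# Spearman under a Gaussian copula.
spearman_to_latent <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Quantile-function mapping of standard-normal draws onto a gene's marginal.
.q_margin <- function(u, spec, gi, log2fc = 0) {
  if (spec$marginal == "lognormal") {
    qlnorm(u, meanlog = spec$meanlog[gi] + log2fc * log(2), sdlog = spec$sdlog[gi])
  } else {
    qnbinom(u, mu = spec$nb_mu[gi] * 2^log2fc, size = spec$nb_size[gi])
  }
}

#' Simulate a two-condition bulk cohort with planted structure
#'
#' Unplanted genes are drawn independently from their marginals; planted DE
#' genes have cancer means scaled by `2^log2fc`; planted pairs achieve their
#' per-condition target Spearman through a Gaussian copula (see
#' [bulk_cohort_spec()]).
#'
#' @param spec A `bulk_cohort_spec`.
#' @return List with `cohort` (a [bulk_cohort()]) and `truth` (planted DE,
#'   planted correlations, marginal family, seed).
#' @export
simulate_bulk <- function(spec) {
  stopifnot(inherits(spec, "bulk_cohort_spec"))
  g <- spec$genes
  lfc <- setNames(numeric(length(g)), g)
  if (!is.null(spec$planted_de)) lfc[names(spec$planted_de)] <- spec$planted_de
  ns <- c(normal = spec$n_normal, cancer = spec$n_cancer)
  expr <- with_seed(spec$seed, {
    mats <- lapply(names(ns), function(cond) {
      n <- ns[[cond]]
      u <- matrix(pnorm(rnorm(length(g) * n)), nrow = length(g))
      if (!is.null(spec$planted_corr)) {
        rho_col <- if (cond == "normal") "rho_normal" else "rho_cancer"
        for (k in seq_len(nrow(spec$planted_corr))) {
          r <- spearman_to_latent(spec$planted_corr[[rho_col]][k])
          z1 <- rnorm(n)
          z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
          u[match(spec$planted_corr$ligand[k], g), ] <- pnorm(z1)
          u[match(spec$planted_corr$receptor[k], g), ] <- pnorm(z2)
        }
      }
      m <- matrix(0, nrow = length(g), ncol = n)
      shift <- if (cond == "cancer") lfc else numeric(length(g))
      for (gi in seq_along(g)) m[gi, ] <- .q_margin(u[gi, ], spec, gi, shift[gi])
      m
    })
    out <- do.call(cbind, mats)
    rownames(out) <- g
    colnames(out) <- c(sprintf("N%03d", seq_len(ns[["normal"]])),
                       sprintf("C%03d", seq_len(ns[["cancer"]])))
    out
  })
  condition <- rep(c("normal", "cancer"), times = ns)
  truth <- list(planted_de = as.list(spec$planted_de %||% setNames(numeric(0), character(0))),
                planted_corr = spec$planted_corr,
                marginal = spec$marginal, seed = spec$seed)
  list(cohort = bulk_cohort(expr, condition), truth = truth)
}

#' Simulate per-sample infiltration fractions
#'
#' Generates lymphocyte/monocyte/neutrophil/stromal fractions in \[0, 1\] for
#' the cohort's cancer samples (independent Beta(2, 5) draws by default; the
#' four compartments are estimated independently and need not sum to one).
#' An optional `association` couples one pair's co-expression to one cell
#' type's fraction: cancer samples are split at the median fraction and the
#' pair's observed values are re-paired within each half by a rank-coupling
#' construction so that the high half attains Spearman `rho_high` and the low
#' half `rho_low`, preserving each gene's marginal values exactly. The
#' (possibly modified) cohort is returned alongside the table.
#'
#' @param cohort A [bulk_cohort()].
#' @param association Optional list with elements `ligand`, `receptor`,
#'   `cell_type`, `rho_high`, `rho_low`.
#' @param seed Integer RNG seed.
#' @return List with `infiltration` (data frame: sample, lymphocyte,
#'   monocyte, neutrophil, stromal) and `cohort`.
#' @export
simulate_infiltration <- function(cohort, association = NULL, seed) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  cancer <- colnames(cohort$expr)[cohort$condition == "cancer"]
  types <- c("lymphocyte", "monocyte", "neutrophil", "stromal")
  with_seed(seed, {
    tab <- data.frame(sample = cancer, stringsAsFactors = FALSE)
    for (ty in types) tab[[ty]] <- rbeta(length(cancer), 2, 5)
    if (!is.null(association)) {
      need <- c("ligand", "receptor", "cell_type", "rho_high", "rho_low")
      if (!all(need %in% names(association)))
        stop("'association' needs elements ", paste(need, collapse = ", "), call. = FALSE)
      lg <- toupper(association$ligand)
      rc <- toupper(association$receptor)
      if (!all(c(lg, rc) %in% rownames(cohort$expr)))
        stop("association genes absent from the cohort", call. = FALSE)
      fr <- tab[[association$cell_type]]
      hi <- cancer[fr > stats::median(fr)]
      lo <- setdiff(cancer, hi)
      for (grp in list(list(s = hi, rho = association$rho_high),
                       list(s = lo, rho = association$rho_low))) {
        n <- length(grp$s)
        if (n < 3L) next
        r <- spearman_to_latent(grp$rho)
        z1 <- rnorm(n)
        z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
        cohort$expr[lg, grp$s] <- sort(cohort$expr[lg, grp$s])[rank(z1, ties.method = "first")]
        cohort$expr[rc, grp$s] <- sort(cohort$expr[rc, grp$s])[rank(z2, ties.method = "first")]
      }
    }
    cohort$infiltration <- tab
    list(infiltration = tab, cohort = cohort)
  })
}

#' Construct a single-cell simulation specification
#'
#' Cells are drawn per (cell, gene) from the cell type's negative-binomial
#' distribution, the standard model for single-cell RNA-seq counts. Each
#' planted communication edge multiplies the ligand's mean in the sender type
#' and the receptor's mean in the receiver type by `elevation`.
#'
#' @param cell_types Named integer vector: cell-type name -> cell count
#'   (at least 2 types).
#' @param genes Character vector of gene symbols.
#' @param mu Baseline NB mean per gene (recycled), shared across types.
#' @param size NB dispersion (size) per gene, recycled.
#' @param planted_edges Optional data frame with columns `sender`,
#'   `receiver`, `ligand`, `receptor`, `elevation` (>= 1; 1 leaves the means
#'   untouched).
#' @param seed Integer RNG seed (mandatory).
#' @return A `single_cell_spec`.
#' @export
single_cell_spec <- function(cell_types, genes, mu = 1, size = 2,
                             planted_edges = NULL, seed) {
  if (missing(seed)) stop("a simulation spec requires an explicit 'seed'", call. = FALSE)
  assert_scalar_number(seed, "seed")
  if (is.null(names(cell_types)) || length(cell_types) < 2L)
    stop("'cell_types' must be a named vector with >= 2 types", call. = FALSE)
  if (any(cell_types < 1)) stop("each cell type needs >= 1 cell", call. = FALSE)
  genes <- toupper(as.character(genes))
  if (anyDuplicated(genes)) stop("duplicate gene symbols in 'genes'", call. = FALSE)
  if (!is.null(planted_edges)) {
    need <- c("sender", "receiver", "ligand", "receptor", "elevation")
    if (!all(need %in% names(planted_edges)))
      stop("'planted_edges' needs columns ", paste(need, collapse = ", "), call. = FALSE)
    planted_edges$ligand <- toupper(planted_edges$ligand)
    planted_edges$receptor <- toupper(planted_edges$receptor)
    if (any(planted_edges$elevation < 1))
      stop("'elevation' must be >= 1 (1 is a no-op)", call. = FALSE)
    bad_t <- setdiff(c(planted_edges$sender, planted_edges$receiver), names(cell_types))
    if (length(bad_t)) stop("unknown cell type(s): ", paste(bad_t, collapse = ", "), call. = FALSE)
    bad_g <- setdiff(c(planted_edges$ligand, planted_edges$receptor), genes)
    if (length(bad_g)) stop("planted genes absent from gene list: ",
                            paste(bad_g, collapse = ", "), call. = FALSE)
  }
  structure(
    list(cell_types = cell_types, genes = genes,
         mu = rep_len(mu, length(genes)), size = rep_len(size, length(genes)),
         planted_edges = planted_edges, seed = as.integer(seed)),
    class = "single_cell_spec"
  )
}

#' Simulate annotated single-cell counts with planted communication edges
#'
#' @param spec A [single_cell_spec()].
#' @return List with `counts` (genes x cells integer matrix), `annotations`
#'   (data frame: cell, cell_type) and `truth` (the planted edge table).
#' @export
simulate_single_cells <- function(spec) {
  stopifnot(inherits(spec, "single_cell_spec"))
  types <- names(spec$cell_types)
  g <- spec$genes
  # per-type mean matrix with planted elevations applied
  mu <- matrix(spec$mu, nrow = length(g), ncol = length(types),
               dimnames = list(g, types))
  if (!is.null(spec$planted_edges)) {
    for (k in seq_len(nrow(spec$planted_edges))) {
      e <- spec$planted_edges[k, ]
      mu[e$ligand, e$sender] <- mu[e$ligand, e$sender] * e$elevation
      mu[e$receptor, e$receiver] <- mu[e$receptor, e$receiver] * e$elevation
    }
  }
  counts <- with_seed(spec$seed, {
    mats <- lapply(types, function(ty) {
      n <- spec$cell_types[[ty]]
      m <- matrix(rnbinom(length(g) * n, mu = rep(mu[, ty], times = n),
                          size = rep(spec$size, times = n)),
                  nrow = length(g))
      colnames(m) <- sprintf("%s_%03d", ty, seq_len(n))
      m
    })
    out <- do.call(cbind, mats)
    rownames(out) <- g
    out
  })
  annotations <- data.frame(
    cell = colnames(counts),
    cell_type = rep(types, times = spec$cell_types),
    stringsAsFactors = FALSE
  )
  list(counts = counts, annotations = annotations, truth = spec$planted_edges)
}

#' Write / read a truth record as JSON
#'
#' Truth records (planted fold-changes, correlations, edges) round-trip
#' losslessly through JSON so simulated datasets can live on disk next to
#' their ground truth.
#'
#' @param truth A truth list as returned by the simulators.
#' @param path File path.
#' @return `path` (write) or the truth list (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
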