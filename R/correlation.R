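# Per-pair Spearman correlation within each condition, random-pair nulls,
# distribution summaries and Kolmogorov-Smirnov comparison.

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (ties averaged), delegated to
#' `stats::cor(method = "spearman")` after validation. A constant vector has
#' no defined rank correlation: the result is `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA` for a constant input.
#' @export
spearman <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("inputs must be numeric", call. = FALSE)
  if (length(x) != length(y)) stop("inputs must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("inputs contain missing values", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

# Correlation of each database ligand against the element-wise sum of its
# measured receptors, over the given sample columns of a plain matrix.
# Shared by the condition-wise, noise-band and infiltration stages.
pair_correlations_matrix <- function(expr, db, samples = colnames(expr)) {
  m <- expr[, samples, drop = FALSE]
  n <- ncol(m)
  out <- vector("list", length(db$ligands))
  skipped <- 0L
  for (i in seq_along(db$ligands)) {
    lg <- db$ligands[i]
    if (!lg %in% rownames(m)) { skipped <- skipped + 1L; next }
    recs <- intersect(db$receptor_groups[[lg]], rownames(m))
    if (!length(recs)) { skipped <- skipped + 1L; next }
    rsum <- colSums(m[recs, , drop = FALSE])
    rho <- suppressWarnings(spearman(m[lg, ], rsum))
    if (is.na(rho)) { skipped <- skipped + 1L; next }
    out[[i]] <- data.frame(ligand = lg,
                           receptors = paste(recs, collapse = ";"),
                           rho = rho, n = n, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(NULL)
  attr(res, "skipped") <- skipped
  res
}

#' Per-pair Spearman correlations within one condition
#'
#' For each ligand in the database with at least one measured receptor,
#' computes the Spearman correlation between the ligand's expression and the
#' element-wise sum of its cognate receptors' expression (linear scale)
#' across the condition's samples. Summing over the receptor group is how
#' non-bijective (one ligand, several receptors) relationships are handled.
#' Pairs whose genes are absent, or whose expression is constant, are
#' skipped and counted in the `skipped` attribute.
#'
#' @param cohort A [bulk_cohort()].
#' @param db A `pair_db`.
#' @param condition `"normal"` or `"cancer"` (>= 3 samples required).
#' @return Data frame: `ligand`, `receptors` (`;`-joined group), `condition`,
#'   `rho`, `n`, `class = "specific"`; attribute `skipped`.
#' @export
pair_correlations <- function(cohort, db, condition = c("normal", "cancer")) {
  stopifnot(inherits(cohort, "bulk_cohort"), inherits(db, "pair_db"))
  condition <- match.arg(condition)
  samples <- colnames(cohort$expr)[cohort$condition == condition]
  if (length(samples) < 3L)
    stop("condition '", condition, "' has fewer than 3 samples", call. = FALSE)
  res <- pair_correlations_matrix(cohort$expr, db, samples)
  if (is.null(res))
    stop("no ligand-receptor pair has both sides measured", call. = FALSE)
  skipped <- attr(res, "skipped")
  res$condition <- condition
  res$class <- "specific"
  res <- res[, c("ligand", "receptors", "condition", "rho", "n", "class")]
  attr(res, "skipped") <- skipped
  res
}

#' Summarize a correlation-coefficient distribution
#'
#' @param records Data frame with a `rho` column, or a numeric vector, with
#'   at least 2 non-missing values.
#' @return One-row data frame: `n`, `mean`, `sd`, `cv` where
#'   `cv = sd / |mean|` (reported as `NA` when `|mean| < 1e-12`).
#' @export
summarize_distribution <- function(records) {
  rho <- if (is.data.frame(records)) records$rho else records
  rho <- rho[!is.na(rho)]
  if (length(rho) < 2L) stop("need at least 2 correlation values", call. = FALSE)
  m <- mean(rho)
  s <- sd(rho)
  data.frame(n = length(rho), mean = m, sd = s,
             cv = if (abs(m) < 1e-12) NA_real_ else s / abs(m))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum absolute difference of the two empirical CDFs; the
#' p-value uses the asymptotic Kolmogorov distribution (the null being that
#' both samples come from the same continuous distribution).
#'
#' @param a,b Numeric vectors (or data frames with a `rho` column); both
#'   non-empty.
#' @return A `ks_result` list: `D`, `p`, `n_a`, `n_b`.
#' @export
ks_compare <- function(a, b) {
  if (is.data.frame(a)) a <- a$rho
  if (is.data.frame(b)) b <- b$rho
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  structure(list(D = unname(kt$statistic), p = unname(kt$p.value),
                 n_a = length(a), n_b = length(b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample K-S: D = %.4f, p = %.3g (n = %d vs %d)\n",
              x$D, x$p, x$n_a, x$n_b))
  invisible(x)
}

#' Random-pair null correlation distribution
#'
#' Spearman correlations for randomly sampled non-interacting
#' (ligand, receptor) combinations, the background against which the
#' specific-pair distribution is compared. Random pairs have no defined
#' cognate group, so no receptor summation is applied.
#'
#' @param cohort A [bulk_cohort()].
#' @param db A `pair_db`.
#' @param n_sample Number of random pairs (>= 100).
#' @param seed Integer RNG seed.
#' @param condition `"normal"` or `"cancer"`.
#' @return Data frame: `ligand`, `receptor`, `condition`, `rho`, `n`,
#'   `class = "random"`; pairs with unmeasured or constant genes are dropped
#'   and counted in the `skipped` attribute.
#' @export
random_null <- function(cohort, db, n_sample, seed,
                        condition = c("normal", "cancer")) {
  stopifnot(inherits(cohort, "bulk_cohort"), inherits(db, "pair_db"))
  condition <- match.arg(condition)
  if (n_sample < 100) stop("'n_sample' must be >= 100 for a stable null", call. = FALSE)
  samples <- colnames(cohort$expr)[cohort$condition == condition]
  if (length(samples) < 3L)
    stop("condition '", condition, "' has fewer than 3 samples", call. = FALSE)
  rp <- sample_random_pairs(db, n_sample, seed = seed, exclude_known = TRUE)
  m <- cohort$expr[, samples, drop = FALSE]
  keep <- rp$ligand %in% rownames(m) & rp$receptor %in% rownames(m)
  rp <- rp[keep, , drop = FALSE]
  rho <- vapply(seq_len(nrow(rp)), function(i) {
    suppressWarnings(spearman(m[rp$ligand[i], ], m[rp$receptor[i], ]))
  }, numeric(1))
  res <- data.frame(ligand = rp$ligand, receptor = rp$receptor,
                    condition = condition, rho = rho, n = ncol(m),
                    class = "random", stringsAsFactors = FALSE)
  res <- res[!is.na(res$rho), , drop = FALSE]
  attr(res, "skipped") <- n_sample - nrow(res)
  res
}
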