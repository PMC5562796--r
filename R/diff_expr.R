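# Differential expression between normal and cancer: per-gene linear model,
# empirical-Bayes moderated t-statistics, threshold selection, and the
# four-scenario classification of ligand-receptor pair regulation.

#' Two-group design matrix with indicator coding
#'
#' Builds the n x 2 design (intercept, cancer indicator) so that the second
#' coefficient is the cancer-minus-normal difference of group means.
#'
#' @param condition Character vector of `"normal"`/`"cancer"` per sample.
#' @return Numeric matrix with columns `intercept`, `cancer`.
#' @export
make_design <- function(condition) {
  condition <- as.character(condition)
  if (!all(condition %in% c("normal", "cancer")))
    stop("'condition' values must be 'normal' or 'cancer'", call. = FALSE)
  cbind(intercept = 1, cancer = as.numeric(condition == "cancer"))
}

#' Fit the per-gene linear model
#'
#' Ordinary least squares of log2(expression + pseudocount) on the design,
#' gene by gene (vectorized over genes). With indicator coding the contrast
#' coefficient equals the difference of group means.
#'
#' @param cohort A [bulk_cohort()].
#' @param design Optional design matrix; defaults to
#'   `make_design(cohort$condition)`. Must have full column rank.
#' @param log2_transform Apply `log2(x + pseudocount)` first? Default `TRUE`.
#' @param pseudocount Pseudocount for the log transform. Default 1.
#' @return An `lr_fits` list: `coef` (contrast per gene), `s2` (residual
#'   variance), `df` (residual degrees of freedom), `stdev_unscaled`
#'   (contrast standard error divided by the residual standard deviation).
#' @export
fit_linear_model <- function(cohort, design = NULL, log2_transform = TRUE,
                             pseudocount = 1) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  n_by_group <- table(cohort$condition)
  if (any(n_by_group < 2L))
    stop("each group needs at least 2 samples", call. = FALSE)
  X <- design %||% make_design(cohort$condition)
  X <- as.matrix(X)
  if (nrow(X) != ncol(cohort$expr))
    stop("design row count must equal the number of samples", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is not of full column rank", call. = FALSE)
  Y <- cohort$expr
  if (log2_transform) Y <- log2(Y + pseudocount)
  XtXinv <- solve(crossprod(X))
  B <- Y %*% X %*% XtXinv                     # genes x m coefficients
  resid <- Y - B %*% t(X)
  d <- nrow(X) - ncol(X)
  s2 <- rowSums(resid^2) / d
  cidx <- ncol(X)                             # contrast = last coefficient
  cf <- B[, cidx]
  names(cf) <- rownames(Y)                    # 1-row matrices drop names
  structure(
    list(genes = rownames(Y), coef = cf, s2 = s2, df = d,
         stdev_unscaled = sqrt(XtXinv[cidx, cidx])),
    class = "lr_fits"
  )
}

# Moment-matching estimate of the scaled-inverse-chi-square prior on
# residual variances: the log variances e_g = log s2_g - digamma(d/2) +
# log(d/2) have mean log s0^2 + digamma(d0/2) - log(d0/2) and excess
# variance trigamma(d0/2) beyond trigamma(d/2). trigamma is inverted by
# bisection (decreasing, tolerance 1e-8).
estimate_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok))
    stop("all residual variances are zero; cannot estimate a variance prior",
         call. = FALSE)
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  target <- var(e) - trigamma(d / 2)
  if (!is.finite(target) || target <= 0)
    return(list(d0 = Inf, s02 = exp(emean)))
  lo <- 1e-8
  hi <- 1e8
  while (hi - lo > 1e-8 * max(1, lo)) {
    mid <- (lo + hi) / 2
    if (trigamma(mid / 2) > target) lo <- mid else hi <- mid
  }
  d0 <- (lo + hi) / 2
  list(d0 = d0, s02 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks each gene's residual variance toward a global prior:
#' `s2_post = (d0 * s02 + d * s2) / (d0 + d)`, with prior degrees of freedom
#' `d0` and scale `s02` estimated by moment matching on the log residual
#' variances. The moderated t is the contrast divided by
#' `sqrt(s2_post) * stdev_unscaled`, with p-values from a t-distribution on
#' `d0 + d` degrees of freedom and Benjamini-Hochberg FDR adjustment.
#'
#' `d0 = 0` reproduces the ordinary t-statistic exactly; `d0 = Inf` uses the
#' common prior variance for every gene.
#'
#' @param fits An `lr_fits` object from [fit_linear_model()].
#' @param d0,s02 Optional overrides of the estimated prior.
#' @return A `de_results` data frame: `gene`, `log2fc`, `t`, `p`, `fdr`;
#'   attributes `d0` and `s02` carry the prior.
#' @export
moderate <- function(fits, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(fits, "lr_fits"))
  if (length(fits$coef) < 10L)
    stop("need at least 10 genes to estimate the variance prior", call. = FALSE)
  prior <- estimate_variance_prior(fits$s2, fits$df)
  if (!is.null(d0)) prior$d0 <- d0
  if (!is.null(s02)) prior$s02 <- s02
  d <- fits$df
  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s02, length(fits$s2))
  } else if (prior$d0 == 0) {
    fits$s2
  } else {
    (prior$d0 * prior$s02 + d * fits$s2) / (prior$d0 + d)
  }
  tstat <- fits$coef / (sqrt(s2_post) * fits$stdev_unscaled)
  df_total <- d + prior$d0
  p <- 2 * pt(-abs(tstat), df = df_total)
  res <- data.frame(
    gene = fits$genes, log2fc = unname(fits$coef), t = unname(tstat),
    p = unname(p), fdr = p.adjust(unname(p), method = "BH"),
    stringsAsFactors = FALSE
  )
  attr(res, "d0") <- prior$d0
  attr(res, "s02") <- prior$s02
  class(res) <- c("de_results", "data.frame")
  res
}

#' Select up-/down-regulated genes by fold-change and p-value thresholds
#'
#' Default gate reproduces the two-fold / p = 0.05 criterion on the raw
#' p-value; set `use_fdr = TRUE` to gate on the BH-adjusted value instead.
#' Boundaries are inclusive.
#'
#' @param results A `de_results` data frame from [moderate()].
#' @param fc_threshold Fold-change threshold on the linear scale (default 2,
#'   i.e. |log2fc| >= 1).
#' @param p_threshold Significance threshold (default 0.05).
#' @param use_fdr Gate on `fdr` instead of raw `p`?
#' @return List with `up` and `down` (character vectors of gene symbols) and
#'   `table` (the results annotated with a `direction` column in
#'   `{"up", "down", "unchanged"}`).
#' @export
select_de <- function(results, fc_threshold = 2, p_threshold = 0.05,
                      use_fdr = FALSE) {
  if (!nrow(results)) stop("'results' is empty", call. = FALSE)
  lfc_cut <- log2(fc_threshold)
  pvals <- if (use_fdr) results$fdr else results$p
  up <- results$gene[results$log2fc >= lfc_cut & pvals <= p_threshold]
  down <- results$gene[results$log2fc <= -lfc_cut & pvals <= p_threshold]
  results$direction <- "unchanged"
  results$direction[results$gene %in% up] <- "up"
  results$direction[results$gene %in% down] <- "down"
  list(up = up, down = down, table = results)
}

#' Classify ligand-receptor pairs by joint regulation scenario
#'
#' Assigns each database pair to exactly one scenario from the two genes'
#' directions: both members up (`both_up`), exactly one member up and the
#' other unchanged (`one_up`), both down (`both_down`), one down and the
#' other unchanged (`one_down`), one up and one down (`discordant`, a case
#' the four canonical scenarios do not cover), or `none`.
#'
#' @param up,down Disjoint character vectors of up-/down-regulated genes.
#' @param db A `pair_db`.
#' @return Data frame: `ligand`, `receptor`, `scenario`.
#' @export
classify_pairs <- function(up, down, db) {
  stopifnot(inherits(db, "pair_db"))
  if (length(intersect(up, down)))
    stop("'up' and 'down' sets overlap", call. = FALSE)
  dir_of <- function(g) ifelse(g %in% up, "up", ifelse(g %in% down, "down", "unchanged"))
  dl <- dir_of(db$pairs$ligand)
  dr <- dir_of(db$pairs$receptor)
  scenario <- mapply(function(a, b) {
    if (a == "up" && b == "up") "both_up"
    else if (a == "down" && b == "down") "both_down"
    else if ((a == "up" && b == "down") || (a == "down" && b == "up")) "discordant"
    else if (a == "up" || b == "up") "one_up"
    else if (a == "down" || b == "down") "one_down"
    else "none"
  }, dl, dr, USE.NAMES = FALSE)
  data.frame(ligand = db$pairs$ligand, receptor = db$pairs$receptor,
             scenario = scenario, stringsAsFactors = FALSE)
}
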