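# Stratification of cancer samples by non-neoplastic infiltration fraction
# and comparison of the pair-correlation distribution between the high- and
# low-infiltration groups.

INFILTRATION_TYPES <- c("lymphocyte", "monocyte", "neutrophil", "stromal")

#' Split samples at the low/high infiltration quantiles
#'
#' Returns the samples in the top and bottom `q` quantiles of one admixture
#' cell type's fraction. Quantiles use linear interpolation of the empirical
#' quantile function; ties with the boundary are included on both sides, so
#' groups can exceed `ceiling(q * n)`.
#'
#' @param table Infiltration data frame: `sample` plus fraction columns
#'   (each in \[0, 1\]).
#' @param cell_type One of `"lymphocyte"`, `"monocyte"`, `"neutrophil"`,
#'   `"stromal"` (or any fraction column present).
#' @param q Quantile (default 0.25).
#' @return List: `high`, `low` (character sample sets), `cell_type`,
#'   `cuts` (the two quantile values). If every fraction is identical the
#'   split is degenerate: both groups contain all samples, with a warning.
#' @export
quantile_split <- function(table, cell_type, q = 0.25) {
  if (!is.data.frame(table) || !"sample" %in% names(table))
    stop("'table' must be a data frame with a 'sample' column", call. = FALSE)
  if (!cell_type %in% names(table))
    stop("unknown cell type column: ", cell_type, call. = FALSE)
  if (q <= 0 || q >= 0.5) stop("'q' must lie in (0, 0.5)", call. = FALSE)
  fr <- table[[cell_type]]
  ok <- !is.na(fr)
  if (sum(ok) < 8L)
    stop("need at least 8 samples with a non-missing fraction", call. = FALSE)
  fr <- fr[ok]
  smp <- table$sample[ok]
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (length(unique(fr)) == 1L) {
    warning("all fractions identical; degenerate split returns both groups in full",
            call. = FALSE)
    return(list(high = smp, low = smp, cell_type = cell_type,
                cuts = c(low = fr[1], high = fr[1])))
  }
  lo_cut <- unname(quantile(fr, q, type = 7))
  hi_cut <- unname(quantile(fr, 1 - q, type = 7))
  list(high = smp[fr >= hi_cut], low = smp[fr <= lo_cut],
       cell_type = cell_type, cuts = c(low = lo_cut, high = hi_cut))
}

#' Compare pair-correlation distributions between infiltration groups
#'
#' Recomputes the specific-pair Spearman correlations within the high- and
#' low-infiltration sample groups and compares the two coefficient
#' distributions by matched quantiles (Q-Q, 99-point grid) and a two-sample
#' Kolmogorov-Smirnov test. A flat Q-Q line on the diagonal and a
#' non-significant K-S p indicate that infiltration content does not drive
#' the correlation structure.
#'
#' @param cohort A [bulk_cohort()] (groups are drawn from its cancer samples).
#' @param db A `pair_db`.
#' @param split A [quantile_split()] result.
#' @return List: `qq` (data frame `prob`, `low`, `high`), `ks` (a
#'   `ks_result`), `n_high`, `n_low` (group sizes).
#' @export
compare_infiltration_groups <- function(cohort, db, split) {
  stopifnot(inherits(cohort, "bulk_cohort"), inherits(db, "pair_db"))
  avail <- colnames(cohort$expr)
  hi <- intersect(split$high, avail)
  lo <- intersect(split$low, avail)
  if (length(hi) < 3L || length(lo) < 3L)
    stop("each infiltration group needs at least 3 samples in the cohort",
         call. = FALSE)
  rho_hi <- pair_correlations_matrix(cohort$expr, db, hi)$rho
  rho_lo <- pair_correlations_matrix(cohort$expr, db, lo)$rho
  probs <- seq(0.01, 0.99, by = 0.01)
  qq <- data.frame(prob = probs,
                   low = unname(quantile(rho_lo, probs, na.rm = TRUE)),
                   high = unname(quantile(rho_hi, probs, na.rm = TRUE)))
  list(qq = qq, ks = ks_compare(rho_hi, rho_lo),
       n_high = length(hi), n_low = length(lo))
}
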