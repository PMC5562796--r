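# Normal-to-cancer correlation-shift classification (areas I/II/III),
# randomized-split noise-band calibration, and cross-cohort recurrence
# ranking.

#' Correlation-shift thresholds
#'
#' The uncorrelated band (-0.25, 0.25) and the correlated (> 0.5) /
#' anticorrelated (< -0.5) cuts. The band is open and the cuts strict, so
#' boundary values fall outside every category.
#'
#' @param low,high Uncorrelated band limits (low < 0 < high).
#' @param correlated Positive-correlation cut (> `high`).
#' @param anticorrelated Negative-correlation cut (< `low`).
#' @return A `shift_thresholds` list.
#' @export
shift_thresholds <- function(low = -0.25, high = 0.25,
                             correlated = 0.5, anticorrelated = -0.5) {
  if (!(low < 0 && 0 < high)) stop("need low < 0 < high", call. = FALSE)
  if (correlated <= high) stop("'correlated' must exceed 'high'", call. = FALSE)
  if (anticorrelated >= low) stop("'anticorrelated' must be below 'low'", call. = FALSE)
  structure(list(low = low, high = high, correlated = correlated,
                 anticorrelated = anticorrelated),
            class = "shift_thresholds")
}

#' Classify a normal-to-cancer correlation shift
#'
#' Category I: uncorrelated in normal, positively correlated in cancer
#' (gained correlation). Category II: negatively correlated in normal,
#' uncorrelated in cancer (lost negative correlation). Category III:
#' positively correlated in normal, uncorrelated in cancer (lost positive
#' correlation). Everything else, including missing coefficients, is `none`;
#' positions with a missing input are flagged in the `missing` attribute.
#'
#' @param rho_normal,rho_cancer Numeric vectors (recycled to equal length)
#'   of Spearman coefficients in \[-1, 1\].
#' @param thresholds A [shift_thresholds()].
#' @return Character vector over `{"I", "II", "III", "none"}` with a
#'   `missing` logical attribute.
#' @export
classify_shift <- function(rho_normal, rho_cancer,
                           thresholds = shift_thresholds()) {
  stopifnot(inherits(thresholds, "shift_thresholds"))
  k <- max(length(rho_normal), length(rho_cancer))
  rho_normal <- rep_len(rho_normal, k)
  rho_cancer <- rep_len(rho_cancer, k)
  ok <- !is.na(rho_normal) & !is.na(rho_cancer)
  if (any(abs(c(rho_normal[ok], rho_cancer[ok])) > 1))
    stop("correlation coefficients must lie in [-1, 1]", call. = FALSE)
  th <- thresholds
  uncor_n <- rho_normal > th$low & rho_normal < th$high
  uncor_c <- rho_cancer > th$low & rho_cancer < th$high
  out <- rep("none", k)
  out[ok & uncor_n & rho_cancer > th$correlated] <- "I"
  out[ok & rho_normal < th$anticorrelated & uncor_c] <- "II"
  out[ok & rho_normal > th$correlated & uncor_c] <- "III"
  attr(out, "missing") <- !ok
  out
}

#' Per-pair shift table for one cohort
#'
#' Computes the specific-pair Spearman correlations in both conditions,
#' merges them by ligand, and classifies the shift of each pair.
#'
#' @param cohort A [bulk_cohort()].
#' @param db A `pair_db`.
#' @param thresholds A [shift_thresholds()].
#' @return Data frame: `ligand`, `receptors`, `rho_normal`, `rho_cancer`,
#'   `category`.
#' @export
shift_table <- function(cohort, db, thresholds = shift_thresholds()) {
  rn <- pair_correlations(cohort, db, "normal")
  rc <- pair_correlations(cohort, db, "cancer")
  tab <- merge(rn[, c("ligand", "receptors", "rho")],
               rc[, c("ligand", "rho")], by = "ligand",
               suffixes = c("_normal", "_cancer"))
  tab$category <- as.character(classify_shift(tab$rho_normal, tab$rho_cancer,
                                              thresholds))
  tab[order(tab$ligand), , drop = FALSE]
}

#' Calibrate the correlation noise band by randomized cohort splits
#'
#' Repeatedly draws two random subsets of `group_size` samples from the
#' normal condition (without replacement within a subset; the two subsets
#' may overlap, as when drawing 2 x 65 from 112 samples), computes every
#' pair's Spearman correlation in each subset, and returns the 95th
#' percentile of |delta rho| pooled over pairs and repetitions — an estimate
#' of how far a correlation coefficient can wander by sampling noise alone.
#'
#' @param cohort A [bulk_cohort()].
#' @param db A `pair_db`.
#' @param group_size Subset size (>= 3; cohort must have > `group_size`
#'   normal samples).
#' @param n_reps Number of random splits (default 1000).
#' @param seed Integer RNG seed.
#' @param prob Percentile of |delta rho| reported (default 0.95).
#' @return Scalar band half-width with attributes `group_size`, `n_reps`.
#' @export
estimate_noise_band <- function(cohort, db, group_size = 65, n_reps = 1000,
                                seed, prob = 0.95) {
  stopifnot(inherits(cohort, "bulk_cohort"), inherits(db, "pair_db"))
  if (group_size < 3) stop("'group_size' must be >= 3", call. = FALSE)
  samples <- colnames(cohort$expr)[cohort$condition == "normal"]
  if (length(samples) < group_size + 1)
    stop("cohort needs more than 'group_size' normal samples", call. = FALSE)
  deltas <- with_seed(seed, {
    unlist(lapply(seq_len(n_reps), function(i) {
      s1 <- sample(samples, group_size)
      s2 <- sample(samples, group_size)
      r1 <- pair_correlations_matrix(cohort$expr, db, s1)
      r2 <- pair_correlations_matrix(cohort$expr, db, s2)
      tab <- merge(r1[, c("ligand", "rho")], r2[, c("ligand", "rho")],
                   by = "ligand")
      tab$rho.x - tab$rho.y
    }))
  })
  band <- unname(quantile(abs(deltas), prob, na.rm = TRUE))
  attr(band, "group_size") <- group_size
  attr(band, "n_reps") <- n_reps
  band
}

#' Rank recurrently shifted pairs across cohorts
#'
#' For each category (I, II, III), pairs are ranked by the number of cohorts
#' in which they fall in that category, ties broken by the mean
#' |rho_cancer - rho_normal| over those cohorts, then lexicographically by
#' pair name (a deterministic, documented tie-break).
#'
#' @param tables Named list of [shift_table()] outputs, one per cohort.
#' @param top_k Rows reported per category (default 15).
#' @return Named list (`I`, `II`, `III`) of data frames: `ligand`,
#'   `receptors`, `n_cohorts`, `mean_shift`.
#' @export
recurrence_rank <- function(tables, top_k = 15) {
  if (!length(tables)) stop("need at least one shift table", call. = FALSE)
  all_tab <- do.call(rbind, lapply(tables, function(t)
    t[, c("ligand", "receptors", "rho_normal", "rho_cancer", "category")]))
  out <- list()
  for (cat in c("I", "II", "III")) {
    sub <- all_tab[all_tab$category == cat, , drop = FALSE]
    if (!nrow(sub)) {
      out[[cat]] <- data.frame(ligand = character(0), receptors = character(0),
                               n_cohorts = integer(0), mean_shift = numeric(0))
      next
    }
    key <- paste(sub$ligand, sub$receptors, sep = "\t")
    agg <- data.frame(
      key = unique(key),
      stringsAsFactors = FALSE
    )
    agg$n_cohorts <- as.integer(table(key)[agg$key])
    agg$mean_shift <- vapply(agg$key, function(k) {
      rows <- sub[key == k, , drop = FALSE]
      mean(abs(rows$rho_cancer - rows$rho_normal))
    }, numeric(1))
    parts <- strsplit(agg$key, "\t", fixed = TRUE)
    agg$ligand <- vapply(parts, `[`, "", 1L)
    agg$receptors <- vapply(parts, `[`, "", 2L)
    agg <- agg[order(-agg$n_cohorts, -agg$mean_shift, agg$ligand, agg$receptors), ]
    agg <- agg[, c("ligand", "receptors", "n_cohorts", "mean_shift")]
    rownames(agg) <- NULL
    out[[cat]] <- head(agg, top_k)
  }
  out
}
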