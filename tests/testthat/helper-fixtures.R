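# Fixture builders shared across the test files. All fixtures are built in
# code; the only packaged file is the 12-pair demo table.

demo_db <- function() {
  load_pairs(system.file("extdata", "demo_pairs.tsv", package = "ligrec"))
}

# Write a pair table to a temp TSV and load it.
db_from_pairs <- function(ligand, receptor) {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(ligand, receptor, sep = "\t"), path)
  load_pairs(path)
}

# n bijective pairs LG001-RC001 ... with unique genes.
bijective_db <- function(n, lig_prefix = "LG", rec_prefix = "RC") {
  db_from_pairs(sprintf("%s%03d", lig_prefix, seq_len(n)),
                sprintf("%s%03d", rec_prefix, seq_len(n)))
}

# Cohort of independent log-normal genes, both conditions.
independent_cohort <- function(genes, n_normal, n_cancer, seed) {
  simulate_bulk(bulk_cohort_spec(genes, n_normal, n_cancer, seed = seed))$cohort
}

# A cohort whose genes cover a bijective db, with per-pair planted
# correlations (rho_normal, rho_cancer recycled over pairs).
planted_pair_cohort <- function(db, rho_normal, rho_cancer, n_normal,
                                n_cancer, seed) {
  pc <- data.frame(ligand = db$pairs$ligand, receptor = db$pairs$receptor,
                   rho_normal = rho_normal, rho_cancer = rho_cancer)
  genes <- unique(c(db$pairs$ligand, db$pairs$receptor))
  simulate_bulk(bulk_cohort_spec(genes, n_normal, n_cancer,
                                 planted_corr = pc, seed = seed))$cohort
}

# Tie-free closed form for the Spearman coefficient.
spearman_closed_form <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Brute-force two-sample K-S D: sup |ECDF_a - ECDF_b| over all data points.
ks_D_brute <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

# All permutations of 1..n as a list of integer vectors.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (k in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}

# Directly constructed high_calls object for network-construction tests.
manual_calls <- function(calls, k = 3) {
  structure(list(calls = calls, k = k, scope = "pooled"),
            class = "high_calls")
}
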