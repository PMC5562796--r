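# Ligand-receptor pair database: loading, validation, querying, and
# non-interacting random pairs for null distributions.

new_pair_db <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("ligand", "receptor") %in% names(pairs)))
  pairs <- pairs[, c("ligand", "receptor")]
  rownames(pairs) <- NULL
  ligands <- sort(unique(pairs$ligand))
  receptors <- sort(unique(pairs$receptor))
  groups <- lapply(split(pairs$receptor, pairs$ligand), function(r) sort(unique(r)))
  structure(
    list(
      pairs = pairs,
      ligands = ligands,
      receptors = receptors,
      receptor_groups = groups[ligands]
    ),
    class = "pair_db"
  )
}

#' Load a ligand-receptor pair table
#'
#' Reads a two-column (ligand, receptor) TSV into a validated, deduplicated
#' pair database. Gene symbols are upper-cased; no alias resolution is
#' attempted. Duplicate (ligand, receptor) rows are collapsed with a warning;
#' rows with fewer than two non-empty fields, or a ligand equal to its
#' receptor, are an error naming the offending line.
#'
#' @param path Path to a tab-separated file with at least two columns:
#'   ligand symbol, receptor symbol. Extra columns are ignored.
#' @param header Logical; does the first line hold column names?
#' @return A `pair_db` object: `$pairs` (data frame of unique records),
#'   `$ligands`, `$receptors` (sorted unique symbol sets) and
#'   `$receptor_groups` (named list mapping each ligand to its receptor set).
#' @seealso [receptor_group()], [sample_random_pairs()], [write_pairs()]
#' @export
load_pairs <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("pair table not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  offset <- 0L
  if (header && length(lines)) {
    lines <- lines[-1L]
    offset <- 1L
  }
  if (!length(lines)) stop("pair table is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lig <- character(length(fields))
  rec <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    f <- f[nzchar(f)]
    if (length(f) < 2L)
      stop(sprintf("malformed pair record at line %d (need ligand and receptor)",
                   i + offset), call. = FALSE)
    lig[i] <- toupper(f[1L])
    rec[i] <- toupper(f[2L])
    if (lig[i] == rec[i])
      stop(sprintf("line %d: ligand and receptor symbols are identical ('%s')",
                   i + offset, lig[i]), call. = FALSE)
  }
  pairs <- data.frame(ligand = lig, receptor = rec, stringsAsFactors = FALSE)
  dup <- duplicated(pairs)
  if (any(dup)) {
    warning(sprintf("%d duplicate pair record(s) removed", sum(dup)),
            call. = FALSE)
    pairs <- pairs[!dup, , drop = FALSE]
  }
  new_pair_db(pairs)
}

#' Write a pair database as a normalized TSV
#'
#' Inverse of [load_pairs()]: reloading the written file (with
#' `header = TRUE`) reproduces an identical database.
#'
#' @param db A `pair_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(db, path) {
  stopifnot(inherits(db, "pair_db"))
  write.table(db$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.pair_db <- function(x, ...) {
  cat(sprintf("pair_db: %d pairs, %d ligands, %d receptors\n",
              nrow(x$pairs), length(x$ligands), length(x$receptors)))
  invisible(x)
}

#' Summary counts of a pair database
#'
#' @param db A `pair_db`.
#' @return Named list with `n_pairs`, `n_ligands`, `n_receptors`.
#' @export
pair_db_counts <- function(db) {
  stopifnot(inherits(db, "pair_db"))
  list(n_pairs = nrow(db$pairs),
       n_ligands = length(db$ligands),
       n_receptors = length(db$receptors))
}

#' Receptors recorded for one ligand
#'
#' One ligand may bind several receptors (non-bijective relationship); the
#' bulk correlation stage correlates the ligand against the sum of this set.
#'
#' @param db A `pair_db`.
#' @param ligand Gene symbol (case-insensitive).
#' @return Character vector of receptor symbols.
#' @export
receptor_group <- function(db, ligand) {
  stopifnot(inherits(db, "pair_db"))
  ligand <- toupper(ligand)
  if (!ligand %in% db$ligands)
    stop("unknown ligand: ", ligand, call. = FALSE)
  db$receptor_groups[[ligand]]
}

#' Number of unordered pairs among n items
#'
#' The arithmetic used for the size of an all-pairs background set:
#' n(n-1)/2. With n = 2,558 curated interactions this gives 3,270,403.
#'
#' @param n Positive integer.
#' @return n(n-1)/2 as a numeric scalar (exact for n well beyond 1e6).
#' @export
count_unordered_pairs <- function(n) {
  assert_scalar_number(n, "n")
  if (n < 1 || n != floor(n)) stop("'n' must be a positive integer", call. = FALSE)
  n * (n - 1) / 2
}

#' Sample random non-interacting ligand-receptor pairs
#'
#' Draws a uniform sample without replacement from the cross product of the
#' database's ligand and receptor symbol sets, optionally excluding the known
#' interacting pairs. These random pairs serve as the background (null)
#' distribution against which specific-pair correlations are compared.
#'
#' @param db A `pair_db`.
#' @param n_sample Number of pairs to draw (>= 1).
#' @param seed Integer RNG seed (mandatory; draws are reproducible).
#' @param exclude_known Drop pairs present in `db$pairs`? Default `TRUE`.
#' @return Data frame with columns `ligand`, `receptor`.
#' @export
sample_random_pairs <- function(db, n_sample, seed, exclude_known = TRUE) {
  stopifnot(inherits(db, "pair_db"))
  assert_scalar_number(n_sample, "n_sample")
  if (n_sample < 1) stop("'n_sample' must be >= 1", call. = FALSE)
  nl <- length(db$ligands)
  nr <- length(db$receptors)
  total <- as.double(nl) * nr
  known <- integer(0)
  if (exclude_known) {
    known <- (match(db$pairs$ligand, db$ligands) - 1L) * nr +
      match(db$pairs$receptor, db$receptors)
    known <- unique(known[!is.na(known)])
  }
  avail <- total - length(known)
  if (n_sample > avail)
    stop(sprintf("requested %d pairs but only %.0f non-interacting combinations exist",
                 n_sample, avail), call. = FALSE)
  idx <- with_seed(seed, {
    if (total <= 5e6) {
      pool <- seq_len(total)
      if (length(known)) pool <- pool[-known]
      sample(pool, n_sample)
    } else {
      # rejection sampling for very large cross products
      known_set <- known
      out <- integer(0)
      while (length(out) < n_sample) {
        cand <- unique(sample.int(total, min(n_sample * 2L, total)))
        cand <- setdiff(cand, known_set)
        out <- unique(c(out, cand))
      }
      out[seq_len(n_sample)]
    }
  })
  data.frame(
    ligand = db$ligands[(idx - 1L) %/% nr + 1L],
    receptor = db$receptors[(idx - 1L) %% nr + 1L],
    stringsAsFactors = FALSE
  )
}
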