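# Directed cell-type communication network from annotated single-cell
# expression: high-expression calling (mean + k*sigma rule), edge
# construction, counting, exclusiveness scoring, top-fraction filtering and
# graph export.

check_annotations <- function(mat, annotations) {
  if (!all(c("cell", "cell_type") %in% names(annotations)))
    stop("'annotations' needs columns 'cell' and 'cell_type'", call. = FALSE)
  missing <- setdiff(colnames(mat), annotations$cell)
  if (length(missing))
    stop("unannotated cell(s): ", paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) " ...", call. = FALSE)
  annotations[match(colnames(mat), annotations$cell), , drop = FALSE]
}

#' Normalize single-cell counts to a common library size
#'
#' Per-cell scaling to `target` total counts followed by a log2(x + 1)
#' transform — the working scale on which the high-expression rule is
#' usually applied. The rule itself is scale-agnostic; normalization is a
#' separate, optional step.
#'
#' @param counts Genes x cells matrix of non-negative counts.
#' @param target Library size to scale to (default 1e4).
#' @param log2 Apply log2(x + 1) after scaling? Default `TRUE`.
#' @return Matrix of the same shape.
#' @export
normalize_cells <- function(counts, target = 1e4, log2 = TRUE) {
  counts <- as.matrix(counts)
  libs <- colSums(counts)
  libs[libs == 0] <- 1
  m <- sweep(counts, 2, libs / target, "/")
  if (log2) m <- base::log2(m + 1)
  m
}

#' Per-cell-type mean expression profiles
#'
#' @param mat Genes x cells expression matrix (any working scale).
#' @param annotations Data frame with `cell`, `cell_type`; every column of
#'   `mat` must be annotated.
#' @return A `cell_type_profiles` list: `means` (genes x types matrix) and
#'   `n_cells` (named counts).
#' @export
type_profiles <- function(mat, annotations) {
  mat <- as.matrix(mat)
  ann <- check_annotations(mat, annotations)
  types <- sort(unique(ann$cell_type))
  means <- vapply(types, function(ty)
    rowMeans(mat[, ann$cell_type == ty, drop = FALSE]),
    numeric(nrow(mat)))
  dimnames(means) <- list(rownames(mat), types)
  structure(list(means = means,
                 n_cells = vapply(types, function(ty) sum(ann$cell_type == ty),
                                  integer(1))),
            class = "cell_type_profiles")
}

#' Call per-type high expression by the mean + k*sigma rule
#'
#' A cell type is called highly expressing gene i when the type's mean
#' expression exceeds a reference mean plus `k` reference standard
#' deviations for that gene. Three reference scopes are provided:
#'
#' * `"pooled"` (default): reference statistics over all single cells
#'   **excluding the evaluated type's own cells**. Excluding the candidate
#'   keeps an elevated subpopulation from inflating its own threshold: with
#'   T equal-sized types a single elevated type contributes enough
#'   between-type variance that its excess over the all-cell mean,
#'   (T-1)/T of the elevation, can never exceed 3 pooled standard
#'   deviations (>= sqrt(T-1)/T of the elevation each), so a
#'   self-including reference would never fire at k = 3.
#' * `"pooled_all"`: the literal self-including pooled reference, kept for
#'   comparison (see above for why it stays silent on balanced designs).
#' * `"per_type"`: reference statistics over the T per-type means. At
#'   k = 3 and T = 7 this can never fire for any input, since the largest
#'   standardized deviation among T values is bounded by (T-1)/sqrt(T)
#'   (about 2.27 for T = 7).
#'
#' Genes with zero reference standard deviation are never called high.
#'
#' @param mat Genes x cells expression matrix (>= 2 cells).
#' @param annotations Data frame with `cell`, `cell_type`.
#' @param k Threshold multiplier (> 0; default 3, tunable).
#' @param scope Reference scope, see above.
#' @return A `high_calls` list: `calls` (types x genes logical matrix),
#'   `k`, `scope`.
#' @export
call_high <- function(mat, annotations, k = 3,
                      scope = c("pooled", "pooled_all", "per_type")) {
  scope <- match.arg(scope)
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 cells", call. = FALSE)
  if (k <= 0) stop("'k' must be positive", call. = FALSE)
  ann <- check_annotations(mat, annotations)
  prof <- type_profiles(mat, annotations)
  types <- colnames(prof$means)
  calls <- matrix(FALSE, nrow = length(types), ncol = nrow(mat),
                  dimnames = list(types, rownames(mat)))
  if (scope == "per_type") {
    xbar <- rowMeans(prof$means)
    sigma <- row_sds(prof$means)
    thr <- xbar + k * sigma
    for (ty in types) calls[ty, ] <- sigma > 0 & prof$means[, ty] > thr
  } else if (scope == "pooled_all") {
    xbar <- rowMeans(mat)
    sigma <- row_sds(mat)
    thr <- xbar + k * sigma
    for (ty in types) calls[ty, ] <- sigma > 0 & prof$means[, ty] > thr
  } else {
    for (ty in types) {
      ref <- mat[, ann$cell_type != ty, drop = FALSE]
      if (ncol(ref) < 2L)
        stop("reference for type '", ty, "' has fewer than 2 cells", call. = FALSE)
      xbar <- rowMeans(ref)
      sigma <- row_sds(ref)
      calls[ty, ] <- sigma > 0 & prof$means[, ty] > xbar + k * sigma
    }
  }
  structure(list(calls = calls, k = k, scope = scope), class = "high_calls")
}

empty_edges <- function() {
  data.frame(sender = character(0), receiver = character(0),
             ligand = character(0), receptor = character(0),
             stringsAsFactors = FALSE)
}

#' Build the directed communication network
#'
#' For every database pair (L, R) and every ordered pair of cell types
#' (s, r) with L called high in s and R called high in r, emits a directed
#' edge s -> r labeled (L, R). Autocrine edges (s = r) are included.
#'
#' @param calls A `high_calls` object from [call_high()].
#' @param db A `pair_db`.
#' @return Data frame: `sender`, `receiver`, `ligand`, `receptor`.
#' @export
build_network <- function(calls, db) {
  stopifnot(inherits(calls, "high_calls"), inherits(db, "pair_db"))
  cm <- calls$calls
  genes <- colnames(cm)
  types <- rownames(cm)
  out <- list()
  for (i in seq_len(nrow(db$pairs))) {
    lg <- db$pairs$ligand[i]
    rc <- db$pairs$receptor[i]
    if (!(lg %in% genes && rc %in% genes)) next
    senders <- types[cm[, lg]]
    receivers <- types[cm[, rc]]
    if (!length(senders) || !length(receivers)) next
    grid <- expand.grid(sender = senders, receiver = receivers,
                        stringsAsFactors = FALSE)
    grid$ligand <- lg
    grid$receptor <- rc
    out[[length(out) + 1L]] <- grid
  }
  if (!length(out)) return(empty_edges())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "out.attrs") <- NULL
  res
}

#' Sender x receiver edge-count matrix
#'
#' @param edges Edge data frame from [build_network()].
#' @param types Optional full cell-type set for the matrix dimensions
#'   (defaults to the types seen in `edges`).
#' @return Integer matrix (senders in rows, receivers in columns) whose sum
#'   equals the number of edges.
#' @export
edge_counts <- function(edges, types = NULL) {
  types <- types %||% sort(unique(c(edges$sender, edges$receiver)))
  tab <- table(factor(edges$sender, levels = types),
               factor(edges$receiver, levels = types))
  m <- matrix(as.integer(tab), nrow = length(types),
              dimnames = list(sender = types, receiver = types))
  m
}

#' Exclusiveness score of a gene in a cell type
#'
#' The type's mean expression of the gene divided by the unweighted mean of
#' the per-type means across all cell types: 1 means uniform expression, T
#' (the number of types) means expression confined to that one type.
#'
#' @param profiles A `cell_type_profiles` from [type_profiles()].
#' @param type Cell-type name.
#' @param gene Gene symbol.
#' @return Non-negative score, or `NA` with a warning when the gene's
#'   across-type mean is zero.
#' @export
exclusiveness <- function(profiles, type, gene) {
  stopifnot(inherits(profiles, "cell_type_profiles"))
  if (!type %in% colnames(profiles$means)) stop("unknown cell type: ", type, call. = FALSE)
  if (!gene %in% rownames(profiles$means)) stop("unknown gene: ", gene, call. = FALSE)
  m <- mean(profiles$means[gene, ])
  if (m == 0) {
    warning("gene '", gene, "' has zero mean across all types", call. = FALSE)
    return(NA_real_)
  }
  unname(profiles$means[gene, type] / m)
}

#' Score, rank and keep the top fraction of edges
#'
#' Each edge is scored by the geometric mean of the sender's ligand
#' exclusiveness and the receiver's receptor exclusiveness — symmetric in
#' the two sides and zero when either side is non-exclusive. Edges are
#' sorted by descending score (ties broken lexicographically by ligand,
#' receptor, sender, receiver) and the top `ceiling(top_fraction * N)` are
#' returned.
#'
#' @param edges Edge data frame from [build_network()] (non-empty).
#' @param profiles A `cell_type_profiles`.
#' @param top_fraction Fraction kept (default 0.02, the top 2 percent).
#' @return The filtered edges with a `score` column, ranked.
#' @export
rank_edges <- function(edges, profiles, top_fraction = 0.02) {
  if (!nrow(edges)) stop("'edges' is empty", call. = FALSE)
  stopifnot(inherits(profiles, "cell_type_profiles"))
  score <- vapply(seq_len(nrow(edges)), function(i) {
    a <- exclusiveness(profiles, edges$sender[i], edges$ligand[i])
    b <- exclusiveness(profiles, edges$receiver[i], edges$receptor[i])
    sqrt(a * b)
  }, numeric(1))
  edges$score <- score
  ord <- order(-edges$score, edges$ligand, edges$receptor,
               edges$sender, edges$receiver)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  head(edges, ceiling(top_fraction * nrow(edges)))
}

#' Edges involving a focal cell type
#'
#' Keeps edges where the focal type is sender or receiver (autocrine edges
#' included) — e.g. restricting the network to crosstalk that involves the
#' malignant cells.
#'
#' @param edges Edge data frame.
#' @param focal Cell-type name.
#' @return Subset of `edges`.
#' @export
filter_involving <- function(edges, focal) {
  res <- edges[edges$sender == focal | edges$receiver == focal, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export the communication network as GraphML
#'
#' Writes the directed multigraph (one edge per ligand-receptor pair per
#' sender/receiver type pair, with `ligand`, `receptor` and optional `score`
#' attributes) via igraph.
#'
#' @param edges Edge data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(edges, path) {
  types <- sort(unique(c(edges$sender, edges$receiver)))
  g <- igraph::graph_from_data_frame(
    edges[, c("sender", "receiver",
              intersect(c("ligand", "receptor", "score"), names(edges)))],
    directed = TRUE,
    vertices = data.frame(name = types)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
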