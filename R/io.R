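# Expression matrix I/O: TSV/CSV dense matrices and Matrix Market (MTX)
# sparse triplets with gene/cell label sidecars.

#' Read an expression matrix
#'
#' Reads a genes x samples (or genes x cells) matrix from TSV, CSV or Matrix
#' Market format. Labels must be unique; values must be finite and
#' non-negative; any missing value is an error. Matrices stored the other
#' way around can be flipped with `transpose = TRUE`.
#'
#' @param path Matrix file. Format is inferred from the extension
#'   (`.mtx` -> MTX, `.csv` -> CSV, otherwise TSV) unless given explicitly.
#' @param format `"auto"`, `"tsv"`, `"csv"` or `"mtx"`.
#' @param genes_path,cells_path For MTX input: one-column text files with
#'   row (gene) and column (cell) labels.
#' @param transpose Flip the matrix after reading?
#' @return Dense numeric matrix with dimnames.
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                                   genes_path = NULL, cells_path = NULL,
                                   transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", "tsv")
  }
  if (format == "mtx") {
    if (is.null(genes_path) || is.null(cells_path))
      stop("MTX input needs 'genes_path' and 'cells_path'", call. = FALSE)
    m <- as.matrix(Matrix::readMM(path))
    rn <- read.delim(genes_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
    cn <- read.delim(cells_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("label files do not match the matrix dimensions", call. = FALSE)
    dimnames(m) <- list(rn, cn)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    labels <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- labels
  }
  if (anyDuplicated(rownames(m))) {
    dups <- unique(rownames(m)[duplicated(rownames(m))])
    stop("duplicate gene symbols: ", paste(head(dups, 10), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample/cell labels", call. = FALSE)
  if (anyNA(m) || any(!is.finite(m)))
    stop("matrix contains missing or non-finite values", call. = FALSE)
  if (any(m < 0)) stop("matrix contains negative values", call. = FALSE)
  if (transpose) m <- t(m)
  m
}

#' Write an expression matrix
#'
#' TSV/CSV output carries the gene labels in a leading `gene` column (the
#' layout [read_expression_matrix()] expects back); MTX output writes the
#' sparse triplets plus gene/cell label sidecars.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path; format inferred from the extension unless given.
#' @param format `"auto"`, `"tsv"`, `"csv"` or `"mtx"`.
#' @param genes_path,cells_path Sidecar label paths for MTX output
#'   (default `<path>.genes.tsv` / `<path>.cells.tsv`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path,
                                    format = c("auto", "tsv", "csv", "mtx"),
                                    genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", "tsv")
  }
  if (format == "mtx") {
    genes_path <- genes_path %||% paste0(path, ".genes.tsv")
    cells_path <- cells_path %||% paste0(path, ".cells.tsv")
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), path)
    writeLines(rownames(mat), genes_path)
    writeLines(colnames(mat), cells_path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a per-sample condition table
#'
#' Two-column TSV (`sample`, `condition`) with condition values
#' `normal`/`cancer`.
#'
#' @param path TSV path.
#' @return Data frame `sample`, `condition`.
#' @export
read_conditions <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(df)))
    stop("condition table needs columns 'sample' and 'condition'", call. = FALSE)
  df
}
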