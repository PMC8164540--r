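# Expression-matrix container and readers/writers.
#
# An expression matrix is a plain numeric matrix, genes in rows and cells in
# columns, with unique rownames (gene ids) and colnames (cell ids). Helper
# functions validate that contract rather than wrapping it in a new class.

#' Validate a genes-by-cells expression matrix
#'
#' Checks the contract every downstream step relies on: a numeric matrix with
#' unique gene rownames and cell colnames, non-negative finite values, and at
#' least three genes (pairwise correlation needs `n_m - 2 >= 1` degrees of
#' freedom).
#'
#' @param values Numeric matrix, genes in rows, cells in columns.
#' @param gene_ids,cell_ids Optional character vectors overriding the
#'   dimnames of `values`.
#' @return The validated matrix with dimnames set, invisibly usable anywhere
#'   an expression matrix is expected.
#' @examples
#' m <- expression_matrix(matrix(rpois(12, 5), 4, 3))
#' dim(m)
#' @export
expression_matrix <- function(values, gene_ids = NULL, cell_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x cells).")
  }
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(cell_ids)) colnames(values) <- cell_ids
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("gene", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("cell", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) abort("Duplicate gene ids.")
  if (anyDuplicated(colnames(values))) abort("Duplicate cell ids.")
  if (nrow(values) < 3L) {
    abort("At least 3 genes are required (t-statistic needs n_m - 2 >= 1).")
  }
  if (any(!is.finite(values))) abort("Expression values must be finite.")
  if (any(values < 0)) abort("Expression values must be non-negative.")
  values
}

#' Read an expression matrix from CSV/TSV or MatrixMarket files
#'
#' CSV/TSV layout: genes as rows, header row of cell ids, first column of
#' gene ids. MatrixMarket layout: an `.mtx` file plus sidecar text files with
#' one gene id and one cell id per line.
#'
#' @param path Path to the CSV/TSV or MTX file.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"mtx"`. `"auto"` guesses
#'   from the file extension.
#' @param genes_file,cells_file Sidecar id files, required for `"mtx"`.
#' @return A validated genes-by-cells numeric matrix.
#' @export
read_expression <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                            genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Expression file not found: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
      abort(sprintf("Cannot guess format from extension of '%s'.", path))
    )
  }
  if (format == "mtx") {
    if (is.null(genes_file) || is.null(cells_file)) {
      abort("MTX input needs `genes_file` and `cells_file` sidecars.")
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_file)
    cells <- readLines(cells_file)
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      abort("MTX dimensions do not match sidecar id files.")
    }
    return(expression_matrix(m, gene_ids = genes, cell_ids = cells))
  }
  delim <- if (format == "csv") "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 2L) abort(sprintf("Malformed expression table: %s", path))
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  expression_matrix(m, gene_ids = genes, cell_ids = colnames(df)[-1L])
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; values are written at full precision so a
#' write/read round trip reproduces the matrix.
#'
#' @param expr Genes-by-cells numeric matrix.
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("auto", "csv", "tsv", "mtx"),
                             genes_file = NULL, cells_file = NULL) {
  expr <- expression_matrix(expr)
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
      abort(sprintf("Cannot guess format from extension of '%s'.", path))
    )
  }
  if (format == "mtx") {
    if (is.null(genes_file) || is.null(cells_file)) {
      abort("MTX output needs `genes_file` and `cells_file` sidecars.")
    }
    Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE), path)
    writeLines(rownames(expr), genes_file)
    writeLines(colnames(expr), cells_file)
    return(invisible(path))
  }
  df <- tibble::as_tibble(expr, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(expr)), df)
  if (format == "csv") {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}
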