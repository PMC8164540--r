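# Cell-cell network construction: pairwise Pearson correlation between cell
# expression profiles, a t-statistic (or Fisher z) significance transform,
# and a correlation threshold that decides which cell pairs become edges.

#' Pairwise Pearson correlations between cells
#'
#' Computes the cell-by-cell Pearson correlation matrix across genes. Each
#' correlation uses all `n_m` genes (the number of rows), which is also the
#' sample size entering the t-statistic of [correlation_t_statistic()].
#'
#' Cells whose expression is constant across genes have no defined
#' correlation; their rows/columns are set to 0 (diagonal stays 1) and a
#' warning names them.
#'
#' @param expr Genes-by-cells numeric matrix (see [expression_matrix()]).
#' @param transform `"log1p"` (default) applies `log(1 + x)` before
#'   correlating, the usual variance stabilization for non-negative
#'   single-cell counts; `"none"` correlates the values as given.
#' @return An object of class `cell_corr`: a list with `r` (cells x cells
#'   correlation matrix), `n_m` (number of genes) and `zero_variance_cells`.
#' @examples
#' sim <- simulate_expression(n_genes = 50, n_cells = 12, n_clusters = 2,
#'                            within_rho = 0.8, seed = 1)
#' cc <- pearson_matrix(sim$matrix)
#' range(cc$r)
#' @export
pearson_matrix <- function(expr, transform = c("log1p", "none")) {
  expr <- expression_matrix(expr)
  transform <- match.arg(transform)
  x <- if (transform == "log1p") log1p(expr) else expr
  sds <- apply(x, 2L, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(stats::cor(x, method = "pearson"))
  if (any(flat)) {
    warn(sprintf(
      "Zero-variance cell(s) %s: correlations set to 0.",
      paste(colnames(x)[flat], collapse = ", ")
    ))
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  diag(r) <- 1
  structure(
    list(r = r, n_m = nrow(expr),
         zero_variance_cells = colnames(x)[flat], transform = transform),
    class = "cell_corr"
  )
}

#' @export
print.cell_corr <- function(x, ...) {
  cat(sprintf("<cell_corr> %d cells, n_m = %d genes (transform: %s)\n",
              ncol(x$r), x$n_m, x$transform))
  invisible(x)
}

#' t-statistic for a Pearson correlation
#'
#' `T = r * sqrt(n_m - 2) / sqrt(1 - r^2)`, distributed as t with `n_m - 2`
#' degrees of freedom under the null of zero correlation. Monotone increasing
#' in `r` for fixed `n_m`. `|r| = 1` returns signed `Inf`.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @param n_m Number of genes each correlation was computed over (`>= 3`).
#' @return Numeric vector of t-statistics.
#' @examples
#' correlation_t_statistic(0.5, 27)
#' @export
correlation_t_statistic <- function(r, n_m) {
  if (!is_count(n_m, min = 3L)) abort("`n_m` must be an integer >= 3.")
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    abort("`r` must lie in [-1, 1].")
  }
  out <- r * sqrt(n_m - 2) / sqrt(1 - r^2)
  out[r == 1] <- Inf
  out[r == -1] <- -Inf
  out
}

#' Fisher z-statistic for a Pearson correlation
#'
#' `z = atanh(r) * sqrt(n_m - 3)`, approximately standard normal under the
#' null. Offered as an alternative significance transform to the t-statistic;
#' both are monotone in `r`, so either can back a correlation threshold.
#'
#' @inheritParams correlation_t_statistic
#' @return Numeric vector of z-statistics.
#' @export
correlation_fisher_z <- function(r, n_m) {
  if (!is_count(n_m, min = 4L)) abort("`n_m` must be an integer >= 4.")
  if (any(!is.finite(r)) || any(abs(r) > 1)) abort("`r` must lie in [-1, 1].")
  atanh(r) * sqrt(n_m - 3)
}

#' Build the cell-cell graph by thresholding correlations
#'
#' Creates an undirected simple graph over cells with an edge wherever the
#' pairwise Pearson correlation is at least `threshold` (pairs are excluded
#' only when strictly below it, so a correlation exactly at the threshold
#' keeps its edge). Only
#' positive correlations create edges; the default 0.27 follows the
#' correlation cutoff used for single-cell networks of this kind.
#'
#' @param corr A `cell_corr` object from [pearson_matrix()], or a symmetric
#'   correlation matrix with cell names.
#' @param threshold Correlation cutoff in (-1, 1); default 0.27.
#' @return An `igraph` undirected graph with edge attribute `r` and graph
#'   attribute `threshold`.
#' @examples
#' sim <- simulate_expression(n_genes = 80, n_cells = 15, n_clusters = 3,
#'                            within_rho = 0.9, seed = 1)
#' g <- build_cell_graph(pearson_matrix(sim$matrix))
#' igraph::ecount(g)
#' @export
build_cell_graph <- function(corr, threshold = 0.27) {
  r <- if (inherits(corr, "cell_corr")) corr$r else corr
  if (!is.matrix(r) || nrow(r) != ncol(r)) {
    abort("`corr` must be a square correlation matrix or a cell_corr object.")
  }
  if (max(abs(r - t(r))) > 1e-8) abort("Correlation matrix must be symmetric.")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= -1 || threshold >= 1) {
    abort("`threshold` must be a single value in (-1, 1).")
  }
  if (is.null(rownames(r))) {
    rownames(r) <- colnames(r) <- paste0("cell", seq_len(nrow(r)))
  }
  n <- nrow(r)
  keep <- r >= threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- rownames(r)
  if (nrow(idx) > 0L) {
    g <- igraph::add_edges(g, t(idx))
    igraph::E(g)$r <- r[idx]
  }
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Edge list of a cell graph as a tibble
#'
#' @param graph An undirected `igraph` cell graph.
#' @return A tibble with columns `cell_i`, `cell_j` and, when present on the
#'   graph, the edge correlation `r`.
#' @export
as_edge_tibble <- function(graph) {
  graph <- check_cell_graph(graph)
  el <- igraph::as_edgelist(graph, names = TRUE)
  out <- tibble::tibble(cell_i = el[, 1L], cell_j = el[, 2L])
  if ("r" %in% igraph::edge_attr_names(graph)) {
    out$r <- igraph::E(graph)$r
  }
  out
}
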