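# ERGM sufficient statistics and change statistics for undirected simple
# graphs. Terms: edges, two-stars sum(choose(deg, 2)), triangles, and the
# geometrically weighted degree / edgewise-shared-partner statistics with a
# fixed decay. Change statistics are the workhorse: both the Metropolis
# sampler and the pseudolikelihood are built from them, so the intractable
# ERGM normalizing constant never has to be evaluated.

.ergm_terms <- c("edges", "two_stars", "triangles", "gw_degree", "gwesp")
.gw_terms <- c("gw_degree", "gwesp")

#' ERGM term configuration
#'
#' Chooses the network summary statistics entering the ERGM and fixes the
#' decay of the geometrically weighted terms. `edges` is always included.
#' The decay is a fixed constant, not estimated: curved-ERGM decay
#' estimation is out of scope.
#'
#' @param terms Character vector from `"edges"`, `"two_stars"`,
#'   `"triangles"`, `"gw_degree"`, `"gwesp"`.
#' @param decay Positive decay for the geometrically weighted terms; either
#'   a single value or a named vector (names in `gw_degree`, `gwesp`).
#' @return A `stat_config` object.
#' @examples
#' stat_config(c("edges", "two_stars", "gwesp", "gw_degree"), decay = 0.5)
#' @export
stat_config <- function(terms = c("edges", "two_stars", "gwesp", "gw_degree"),
                        decay = 0.5) {
  terms <- unique(as.character(terms))
  bad <- setdiff(terms, .ergm_terms)
  if (length(bad)) {
    abort(sprintf("Unknown ERGM term(s): %s", paste(bad, collapse = ", ")))
  }
  if (!"edges" %in% terms) abort("`edges` must always be included.")
  gw <- intersect(terms, .gw_terms)
  dec <- setNames(rep(NA_real_, length(gw)), gw)
  if (length(gw)) {
    if (is.null(names(decay))) {
      if (!length(decay) %in% c(1L, length(gw))) {
        abort("`decay` must be length 1 or match the gw terms.")
      }
      dec[] <- decay
    } else {
      missing <- setdiff(gw, names(decay))
      if (length(missing)) {
        abort(sprintf("`decay` missing for: %s", paste(missing, collapse = ", ")))
      }
      dec[gw] <- decay[gw]
    }
    if (any(!is.finite(dec)) || any(dec <= 0)) abort("`decay` must be > 0.")
  }
  structure(list(terms = terms, decay = dec), class = "stat_config")
}

#' @export
print.stat_config <- function(x, ...) {
  dec <- if (length(x$decay)) {
    paste0(" (decay ", paste(sprintf("%s=%g", names(x$decay), x$decay),
                             collapse = ", "), ")")
  } else ""
  cat(sprintf("<stat_config> %s%s\n", paste(x$terms, collapse = ", "), dec))
  invisible(x)
}

# weight of an edge with k shared partners / a node of degree k:
# w(k) = e^lambda * (1 - (1 - e^-lambda)^k); w(0) = 0.
gw_weight <- function(k, lambda) {
  exp(lambda) * (1 - (1 - exp(-lambda))^k)
}

#' Network summary statistics
#'
#' Computes the configured ERGM sufficient statistics of an undirected
#' simple graph: `edges` = |E|; `two_stars` = sum over nodes of
#' `choose(degree, 2)`; `triangles` = number of 3-cliques;
#' `gw_degree(lambda)` = `e^lambda * sum_k [1 - (1 - e^-lambda)^k] * D_k`
#' over the degree distribution `D_k`; `gwesp(lambda)` = the same weighting
#' applied to `EP_k`, the number of edges with exactly `k` shared partners.
#'
#' @param graph Undirected simple `igraph` graph.
#' @param config A [stat_config()].
#' @return Named numeric vector aligned with `config$terms`.
#' @examples
#' network_statistics(igraph::make_full_graph(3), stat_config(c("edges",
#'   "two_stars", "triangles")))
#' @export
network_statistics <- function(graph, config = stat_config()) {
  graph <- check_cell_graph(graph)
  A <- graph_adjacency(graph)
  stats_from_adjacency(A, config)
}

stats_from_adjacency <- function(A, config) {
  deg <- rowSums(A)
  need_sp <- any(c("triangles", "gwesp") %in% config$terms)
  if (need_sp) AA <- A %*% A
  vapply(config$terms, function(term) {
    switch(term,
      edges = sum(A) / 2,
      two_stars = sum(deg * (deg - 1) / 2),
      triangles = sum((A %*% A) * A) / 6,
      gw_degree = sum(gw_weight(deg, config$decay[["gw_degree"]])),
      gwesp = {
        up <- upper.tri(A) & A == 1
        sum(gw_weight(AA[up], config$decay[["gwesp"]]))
      }
    )
  }, numeric(1L))
}

# Change statistic for dyad (i, j): S(Y with edge ij) - S(Y without edge ij),
# computed from the adjacency with the edge treated as absent. `deg` is the
# current degree vector (including the edge if present).
delta_dyad <- function(A, deg, i, j, config) {
  Aij <- A[i, j]
  row_i <- A[i, ]; row_i[j] <- 0
  row_j <- A[j, ]; row_j[i] <- 0
  di <- deg[i] - Aij
  dj <- deg[j] - Aij
  common <- which(row_i > 0 & row_j > 0)
  cn <- length(common)
  vapply(config$terms, function(term) {
    switch(term,
      edges = 1,
      two_stars = di + dj,
      triangles = cn,
      gw_degree = {
        b <- 1 - exp(-config$decay[["gw_degree"]])
        b^di + b^dj
      },
      gwesp = {
        lam <- config$decay[["gwesp"]]
        b <- 1 - exp(-lam)
        out <- gw_weight(cn, lam)
        if (cn > 0) {
          Ak <- A[common, , drop = FALSE]
          sp_i <- as.vector(Ak %*% row_i)
          sp_j <- as.vector(Ak %*% row_j)
          out <- out + sum(b^sp_i + b^sp_j)
        }
        out
      }
    )
  }, numeric(1L))
}

#' Change statistics for one dyad
#'
#' Returns `S(Y+) - S(Y-)`, the difference in the configured statistics
#' between the graph with the edge `(i, j)` present and absent. The current
#' state of the dyad does not matter. This is the quantity the Metropolis
#' acceptance ratio and the pseudolikelihood are built from.
#'
#' @param graph Undirected simple `igraph` graph.
#' @param dyad Length-2 vector of vertex names or indices, `i != j`.
#' @param config A [stat_config()].
#' @return Named numeric vector aligned with `config$terms`.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c, simplify = TRUE)
#' change_statistics(g, c("a", "c"),
#'                   stat_config(c("edges", "two_stars", "triangles")))
#' @export
change_statistics <- function(graph, dyad, config = stat_config()) {
  graph <- check_cell_graph(graph)
  if (length(dyad) != 2L) abort("`dyad` must have length 2.")
  idx <- if (is.character(dyad)) {
    match(dyad, igraph::V(graph)$name)
  } else {
    as.integer(dyad)
  }
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > igraph::vcount(graph))) {
    abort("`dyad` does not name two vertices of `graph`.")
  }
  if (idx[1L] == idx[2L]) abort("Self-loop dyads have no change statistic.")
  A <- graph_adjacency(graph)
  delta_dyad(A, rowSums(A), idx[1L], idx[2L], config)
}

# Design matrix of change statistics over all dyads i < j.
# Returns list(i, j, y, X) with X of dimension n_dyads x n_terms.
dyad_design <- function(A, config) {
  n <- nrow(A)
  deg <- rowSums(A)
  n_dyads <- n * (n - 1L) / 2L
  X <- matrix(0, n_dyads, length(config$terms),
              dimnames = list(NULL, config$terms))
  ii <- integer(n_dyads); jj <- integer(n_dyads); y <- numeric(n_dyads)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      ii[k] <- i; jj[k] <- j; y[k] <- A[i, j]
      X[k, ] <- delta_dyad(A, deg, i, j, config)
    }
  }
  list(i = ii, j = jj, y = y, X = X)
}
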