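# Metropolis sampler for ERGMs: single-dyad-toggle proposals whose
# acceptance ratio only needs change statistics, never the normalizing
# constant.

#' Simulate a graph from an ERGM by Metropolis sampling
#'
#' Runs a Metropolis chain over graphs on `n` nodes targeting
#' `P(Y | theta) proportional to exp(theta' S(Y))`. Each step proposes
#' toggling one uniformly chosen dyad and accepts with probability
#' `min(1, exp(+/- theta' delta))` where `delta` is the dyad's change
#' statistic. The chain starts from the empty graph.
#'
#' @param n Number of nodes (`>= 2`).
#' @param theta Coefficient vector aligned with `config$terms`.
#' @param config A [stat_config()].
#' @param n_sweeps Number of single-dyad proposals; default `20 * n^2`.
#' @param seed Integer seed; the same seed and arguments reproduce the same
#'   graph exactly.
#' @param init Optional starting graph (`igraph`, `n` nodes); defaults to
#'   the empty graph.
#' @return An undirected simple `igraph` graph with `n` named vertices.
#' @examples
#' g <- sample_ergm(20, theta = qlogis(0.2), config = stat_config("edges"),
#'                  seed = 1)
#' igraph::ecount(g)
#' @export
sample_ergm <- function(n, theta, config = stat_config(), n_sweeps = NULL,
                        seed = NULL, init = NULL) {
  if (!is_count(n, min = 2L)) abort("`n` must be an integer >= 2.")
  theta <- as.numeric(theta)
  if (length(theta) != length(config$terms)) {
    abort("`theta` length must match the number of configured terms.")
  }
  if (any(!is.finite(theta))) abort("`theta` must be finite.")
  n_sweeps <- n_sweeps %||% (20L * n^2)
  if (!is_count(n_sweeps, min = 1L)) abort("`n_sweeps` must be a positive integer.")

  A <- matrix(0, n, n)
  if (!is.null(init)) {
    init <- check_cell_graph(init, "init")
    if (igraph::vcount(init) != n) abort("`init` must have `n` nodes.")
    A <- graph_adjacency(init)
  }

  run <- function() {
    deg <- rowSums(A)
    pick_i <- sample.int(n, n_sweeps, replace = TRUE)
    pick_j <- sample.int(n - 1L, n_sweeps, replace = TRUE)
    logu <- log(runif(n_sweeps))
    for (s in seq_len(n_sweeps)) {
      i <- pick_i[s]
      j <- pick_j[s]
      if (j >= i) j <- j + 1L  # uniform over the n-1 other nodes
      delta <- delta_dyad(A, deg, i, j, config)
      lr <- sum(theta * delta)
      if (A[i, j] == 1) lr <- -lr  # proposing removal
      if (logu[s] < lr) {
        newval <- 1 - A[i, j]
        A[i, j] <<- newval
        A[j, i] <<- newval
        step <- if (newval == 1) 1 else -1
        deg[i] <- deg[i] + step
        deg[j] <- deg[j] + step
      }
    }
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())

  rownames(A) <- colnames(A) <- paste0("v", seq_len(n))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}
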