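# Internal helpers shared across modules.

# Deterministic fan-out of one user seed into per-stage child seeds, so a
# stage can be re-run in isolation and still match the full pipeline run.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offsets <- c(
    simulate = 101L, graph = 211L, cluster = 307L, hubs = 401L,
    enrich = 503L, restart = 601L, order = 701L
  )
  off <- if (stage %in% names(offsets)) offsets[[stage]] else abs(sum(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + off) %% 2147483647)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

# Validate an undirected simple graph with named vertices; returns the graph
# with names filled in if absent.
check_cell_graph <- function(graph, arg = "graph") {
  if (!igraph::is_igraph(graph)) {
    abort(sprintf("`%s` must be an igraph object.", arg))
  }
  if (igraph::is_directed(graph)) {
    abort(sprintf("`%s` must be undirected.", arg))
  }
  if (igraph::any_multiple(graph) || any(igraph::which_loop(graph))) {
    abort(sprintf("`%s` must be simple (no self-loops or multi-edges).", arg))
  }
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  graph
}

graph_adjacency <- function(graph) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph, type = "both", sparse = TRUE))
  storage.mode(A) <- "double"
  diag(A) <- 0
  A
}
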