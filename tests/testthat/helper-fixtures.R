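# Shared fixtures and independent oracles, all built in code.

k3_graph <- function() {
  g <- igraph::make_full_graph(3)
  igraph::V(g)$name <- paste0("v", 1:3)
  g
}

c4_graph <- function() {
  g <- igraph::make_ring(4)
  igraph::V(g)$name <- paste0("v", 1:4)
  g
}

star_graph <- function(n = 5) {
  g <- igraph::make_star(n, mode = "undirected", center = 1)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

path_graph <- function(n = 5) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

random_graph <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

# Brute-force change-statistic oracle: full recomputation of the summary
# statistics on the graphs with the dyad present and absent.
brute_change <- function(graph, dyad, config) {
  es <- igraph::E(graph)[dyad[1] %--% dyad[2]]
  g_off <- igraph::delete_edges(graph, es)
  g_on <- igraph::add_edges(g_off, dyad)
  network_statistics(g_on, config) - network_statistics(g_off, config)
}

# Adjusted Rand index (chance-corrected partition agreement).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Area under the ROC curve of score rankings for binary truth.
auc_score <- function(truth, score) {
  as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE)))
}

all_terms_config <- function(decay = 0.5) {
  stat_config(c("edges", "two_stars", "triangles", "gw_degree", "gwesp"),
              decay = decay)
}
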