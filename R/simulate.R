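# Simulators providing ground truth for every stage: mixture-ERGM networks
# with known labels, block-correlated expression matrices, and planted hub
# evidence fields.

#' Default within-class ERGM parameters for the three-class fixture
#'
#' Three classes that differ in baseline edge propensity (around 0.4, 0.3
#' and 0.2 before the transitivity term) and share a mild positive
#' edgewise-shared-partner effect, giving dense, internally cohesive blocks
#' that are well separated from the sparse between-class background. Terms
#' are aligned with the default [stat_config()] (edges, two-stars, gwesp,
#' gw-degree).
#'
#' @return List of three named coefficient vectors.
#' @export
default_mixture_theta <- function() {
  terms <- c("edges", "two_stars", "gwesp", "gw_degree")
  list(
    setNames(c(qlogis(0.40), 0, 0.2, 0), terms),
    setNames(c(qlogis(0.30), 0, 0.2, 0), terms),
    setNames(c(qlogis(0.20), 0, 0.2, 0), terms)
  )
}

#' Simulate a network from a mixture of ERGMs with known labels
#'
#' Node labels are drawn from `Multinomial(1, alpha)`. Each within-class
#' subgraph is sampled from its ERGM by [sample_ergm()]; dyads between
#' classes are independent Bernoulli with log-odds `theta_between` (edges
#' between different subnetworks arise at random under this model).
#'
#' @param n Number of nodes.
#' @param alpha Mixing probability vector (length G).
#' @param theta_within List of G coefficient vectors aligned with
#'   `config$terms`; defaults to [default_mixture_theta()] when `G = 3` and
#'   `config` has the default terms.
#' @param theta_between Scalar or `G x G` matrix of between-class edge
#'   log-odds; default `qlogis(0.05)`.
#' @param config A [stat_config()] for the within-class ERGMs.
#' @param seed Integer seed (labels, block samplers and between-class coin
#'   flips all derive from it).
#' @param n_sweeps Metropolis proposals per block; default `20 * n_g^2`.
#' @return A list with `graph` (igraph), `true_labels` (named integer
#'   vector), `true_alpha`, `theta_within`, `theta_between`, `config`,
#'   `seed`.
#' @examples
#' sim <- simulate_mixture_network(n = 30, seed = 1)
#' table(sim$true_labels)
#' @export
simulate_mixture_network <- function(n = 60, alpha = rep(1 / 3, 3),
                                     theta_within = NULL,
                                     theta_between = qlogis(0.05),
                                     config = stat_config(), seed = NULL,
                                     n_sweeps = NULL) {
  if (!is_count(n, min = 2L)) abort("`n` must be an integer >= 2.")
  if (any(alpha < 0) || abs(sum(alpha) - 1) > 1e-8) {
    abort("`alpha` must be a probability vector.")
  }
  G <- length(alpha)
  if (is.null(theta_within)) {
    if (G == 3L && identical(config$terms,
                             c("edges", "two_stars", "gwesp", "gw_degree"))) {
      theta_within <- default_mixture_theta()
    } else {
      abort("`theta_within` must be supplied for non-default alpha/config.")
    }
  }
  if (length(theta_within) != G) {
    abort("`theta_within` must have one coefficient vector per class.")
  }
  if (is.matrix(theta_between)) {
    if (!all(dim(theta_between) == G)) {
      abort("`theta_between` matrix must be G x G.")
    }
  } else {
    theta_between <- matrix(theta_between, G, G)
  }

  draw_labels <- function() sample.int(G, n, replace = TRUE, prob = alpha)
  labels <- if (is.null(seed)) draw_labels() else {
    withr::with_seed(derive_seed(seed, "simulate"), draw_labels())
  }

  A <- matrix(0, n, n)
  for (g in seq_len(G)) {
    idx <- which(labels == g)
    ng <- length(idx)
    if (ng >= 2L) {
      sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, "simulate") + g
      sub <- sample_ergm(ng, theta_within[[g]], config,
                         n_sweeps = n_sweeps, seed = sub_seed)
      A[idx, idx] <- graph_adjacency(sub)
    }
  }
  fill_between <- function() {
    for (g in seq_len(G - 1L)) {
      for (h in (g + 1L):G) {
        ig <- which(labels == g); ih <- which(labels == h)
        if (length(ig) && length(ih)) {
          p <- plogis(theta_between[g, h])
          draws <- matrix(rbinom(length(ig) * length(ih), 1L, p),
                          length(ig), length(ih))
          A[ig, ih] <<- draws
          A[ih, ig] <<- t(draws)
        }
      }
    }
  }
  if (G > 1L) {
    if (is.null(seed)) fill_between() else {
      withr::with_seed(derive_seed(seed, "simulate") + G + 1L, fill_between())
    }
  }
  rownames(A) <- colnames(A) <- paste0("cell", seq_len(n))
  graph <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  list(graph = graph,
       true_labels = setNames(as.integer(labels), rownames(A)),
       true_alpha = alpha, theta_within = theta_within,
       theta_between = theta_between, config = config, seed = seed)
}

#' Simulate a block-correlated expression matrix
#'
#' Cells are assigned to `n_clusters` balanced clusters. Each cell's
#' profile across genes is `sqrt(between_rho) * g + sqrt(within_rho -
#' between_rho) * f_k + sqrt(1 - within_rho) * noise_sd * eps`, where `g`
#' is a shared background program, `f_k` the cluster-specific program and
#' `eps` i.i.d. Gaussian noise, all standard normal across genes. With
#' `noise_sd = 1` the population Pearson correlation between two cells is
#' exactly `within_rho` within a cluster and `between_rho` across clusters.
#' Values are shifted by a constant to be non-negative, which leaves all
#' Pearson correlations unchanged (recorded in the returned parameters).
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param n_clusters Number of cell clusters (`<= n_cells`).
#' @param within_rho,between_rho Target correlations, `0 <= between_rho <=
#'   within_rho < 1`.
#' @param noise_sd Noise scale; values other than 1 shrink the realized
#'   correlations below the targets.
#' @param seed Integer seed.
#' @return A list with `matrix` (genes x cells), `true_cell_labels`,
#'   `within_rho`, `between_rho`, `noise_sd`, `shift`, `seed`.
#' @examples
#' sim <- simulate_expression(100, 12, 3, within_rho = 0.9, seed = 1)
#' dim(sim$matrix)
#' @export
simulate_expression <- function(n_genes = 200, n_cells = 60, n_clusters = 3,
                                within_rho = 0.6, between_rho = 0.05,
                                noise_sd = 1, seed = NULL) {
  if (!is_count(n_genes, 3L) || !is_count(n_cells, 1L)) {
    abort("`n_genes` must be >= 3 and `n_cells` >= 1.")
  }
  if (!is_count(n_clusters, 1L) || n_clusters > n_cells) {
    abort("`n_clusters` must be an integer in [1, n_cells].")
  }
  if (within_rho < 0 || within_rho >= 1 || between_rho < 0 ||
      between_rho > within_rho) {
    abort("Need 0 <= between_rho <= within_rho < 1.")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  labels <- sort(rep_len(seq_len(n_clusters), n_cells))
  build <- function() {
    shared <- rnorm(n_genes)
    programs <- matrix(rnorm(n_genes * n_clusters), n_genes, n_clusters)
    eps <- matrix(rnorm(n_genes * n_cells), n_genes, n_cells)
    x <- sqrt(between_rho) * shared +
      sqrt(within_rho - between_rho) * programs[, labels, drop = FALSE] +
      sqrt(1 - within_rho) * noise_sd * eps
    x
  }
  x <- if (is.null(seed)) build() else {
    withr::with_seed(derive_seed(seed, "simulate"), build())
  }
  shift <- -min(x)
  x <- x + shift
  rownames(x) <- paste0("gene", seq_len(n_genes))
  colnames(x) <- paste0("cell", seq_len(n_cells))
  list(matrix = x,
       true_cell_labels = setNames(labels, colnames(x)),
       within_rho = within_rho, between_rho = between_rho,
       noise_sd = noise_sd, shift = shift, seed = seed)
}

#' Plant a hub field on a graph
#'
#' Draws hub states and matching evidence in the generative direction of
#' the hidden-MRF model: `T_i ~ Bernoulli(frac_hubs)` (optionally refined
#' by one Gibbs sweep under the degree-weighted Ising prior), then
#' `omega_i ~ N(0, 1)` for non-hubs and `omega_i ~ N(mu_star, sigma_star^2)`
#' for hubs.
#'
#' @param graph Undirected simple `igraph` graph.
#' @param labels Unused by the i.i.d. method; kept so the call mirrors
#'   [hub_values()].
#' @param frac_hubs Hub probability in `[0, 1)`.
#' @param mu_star,sigma_star Hub emission mean (`> 0`) and sd.
#' @param seed Integer seed.
#' @param method `"iid"` (default) or `"gibbs"` (one prior sweep under
#'   `hp`; falls back to i.i.d. with a warning on edgeless graphs).
#' @param hp [mrf_hyperparams()] used by the `"gibbs"` method.
#' @return A list with `T_true`, `omega`, `mu_star`, `sigma_star`,
#'   `frac_hubs`, `method`, `seed`.
#' @examples
#' g <- sample_ergm(20, qlogis(0.2), stat_config("edges"), seed = 1)
#' ph <- plant_hub_field(g, frac_hubs = 0.2, seed = 2)
#' sum(ph$T_true)
#' @export
plant_hub_field <- function(graph, labels = NULL, frac_hubs = 0.1,
                            mu_star = 4, sigma_star = 1, seed = NULL,
                            method = c("iid", "gibbs"),
                            hp = mrf_hyperparams()) {
  graph <- check_cell_graph(graph)
  method <- match.arg(method)
  n <- igraph::vcount(graph)
  if (frac_hubs < 0 || frac_hubs >= 1) abort("`frac_hubs` must be in [0, 1).")
  if (mu_star <= 0 || sigma_star <= 0) {
    abort("`mu_star` and `sigma_star` must be positive.")
  }
  if (method == "gibbs" && igraph::ecount(graph) == 0L) {
    warn("Graph has no edges; falling back to i.i.d. hub states.")
    method <- "iid"
  }
  draw <- function() {
    Tv <- rbinom(n, 1L, frac_hubs)
    if (method == "gibbs") {
      ew <- mrf_edge_weights(graph)
      nbr <- lapply(seq_len(n), function(i) {
        k <- which(ew$i == i | ew$j == i)
        cbind(ifelse(ew$i[k] == i, ew$j[k], ew$i[k]), ew$w[k])
      })
      base <- qlogis(max(frac_hubs, 1e-12))
      for (i in seq_len(n)) {
        nb <- nbr[[i]]
        lo <- base
        if (nrow(nb)) {
          Tn <- Tv[nb[, 1L]]
          lo <- lo + hp$tau1 * sum(nb[, 2L] * Tn) -
            hp$tau0 * sum(nb[, 2L] * (1 - Tn))
        }
        Tv[i] <- rbinom(1L, 1L, plogis(lo))
      }
    }
    omega <- rnorm(n, 0, 1)
    if (any(Tv == 1L)) {
      omega[Tv == 1L] <- rnorm(sum(Tv), mu_star, sigma_star)
    }
    list(T_true = Tv, omega = omega)
  }
  res <- if (is.null(seed)) draw() else {
    withr::with_seed(derive_seed(seed, "hubs"), draw())
  }
  nm <- igraph::V(graph)$name
  list(T_true = setNames(res$T_true, nm), omega = setNames(res$omega, nm),
       mu_star = mu_star, sigma_star = sigma_star, frac_hubs = frac_hubs,
       method = method, seed = seed)
}
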