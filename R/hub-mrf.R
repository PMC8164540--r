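# Hub-node prioritization with a Gaussian hidden Markov random field.
#
# Evidence: each node's hub value hv_i = n_i / degree_i (n_i = number of
# distinct cluster labels among its neighbors) is transformed to
# omega_i = qnorm(1 - hv_i / 2). States T_i in {0, 1} mark hub nodes.
# Emission: omega_i | T_i = 0 ~ N(0, 1); omega_i | T_i = 1 ~ N(mu_i,
# sigma_i^2) with a Normal-Inverse-Gamma prior on (mu_i, sigma_i^2).
# Prior on T: a degree-weighted Ising field over the graph edges. Inference
# is a systematic-scan Gibbs sampler over (T, mu, sigma^2); the field's
# normalizing constant (a sum over 2^n configurations) is only ever touched
# in the exact-enumeration validation mode for small n.

#' Hub values of the nodes of a clustered graph
#'
#' `hv_i = n_i / degree_i`, where `n_i` counts the distinct cluster labels
#' among the neighbors of node `i` (the node's own label is not added).
#' Isolated nodes get `hv = 1`, the no-hub-evidence value. The raw ratio
#' already lies in (0, 1]; `rescale = TRUE` additionally min-max rescales
#' into (0, 1] (off by default — the ratio needs no extra normalization).
#'
#' @param graph Undirected simple `igraph` graph.
#' @param labels Cluster label per node: an integer vector in vertex order,
#'   or named by vertex.
#' @param rescale Optional extra min-max rescale (default `FALSE`).
#' @return Named numeric vector of hub values in (0, 1].
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' hub_values(g, c(1, 1, 1, 2, 2))
#' @export
hub_values <- function(graph, labels, rescale = FALSE) {
  graph <- check_cell_graph(graph)
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  if (!is.null(names(labels))) {
    if (!all(nm %in% names(labels))) abort("Some nodes are missing a label.")
    labels <- labels[nm]
  }
  if (length(labels) != n || anyNA(labels)) {
    abort("`labels` must provide one non-missing label per node.")
  }
  labels <- as.integer(as.factor(labels))
  A <- graph_adjacency(graph)
  deg <- rowSums(A)
  hv <- vapply(seq_len(n), function(i) {
    if (deg[i] == 0) return(1)
    nb <- which(A[i, ] > 0)
    length(unique(labels[nb])) / deg[i]
  }, numeric(1L))
  if (rescale && length(unique(hv)) > 1L) {
    hv <- (hv - min(hv)) / (max(hv) - min(hv))
    hv[hv == 0] <- min(hv[hv > 0]) / 2  # keep the open-interval contract
  }
  setNames(hv, nm)
}

#' z-transform of hub values
#'
#' `omega_i = qnorm(1 - hv_i / 2)`, elementwise, after clamping `hv` below
#' at `clamp` so the quantile stays finite. Monotone decreasing in `hv`;
#' `hv = 1` maps to 0. Note the directionality this implies: small hub
#' values (few distinct neighbor clusters per unit degree) produce large
#' omega and hence hub evidence; `invert = TRUE` applies the transform to
#' `1 - hv` instead, so that nodes touching many clusters score high.
#'
#' @param hv Numeric vector in (0, 1].
#' @param clamp Lower clamp for `hv` (default `1e-8`).
#' @param invert Transform `1 - hv` instead of `hv` (default `FALSE`).
#' @return Numeric vector `omega >= 0` (for the default direction).
#' @examples
#' z_transform(c(1, 0.5))
#' @export
z_transform <- function(hv, clamp = 1e-8, invert = FALSE) {
  if (any(!is.finite(hv)) || any(hv <= 0) || any(hv > 1)) {
    abort("`hv` must lie in (0, 1].")
  }
  x <- if (invert) 1 - hv else hv
  x <- pmax(x, clamp)
  out <- qnorm(1 - x / 2)
  if (!is.null(names(hv))) names(out) <- names(hv)
  out
}

#' Hyperparameters of the hub MRF
#'
#' `h` is the external field on hub states, `tau0`/`tau1` the couplings
#' rewarding linked non-hub/hub pairs, each weighted by `d_i + d_j` with
#' `d_i = sqrt(degree_i)`. `(u_bar, a, upsilon, d_scale)` parameterize the
#' Normal-Inverse-Gamma emission prior: `sigma^2 ~ InvGamma(upsilon / 2,
#' upsilon * d_scale / 2)` and `mu | sigma^2 ~ N(u_bar, sigma^2 / a)`.
#'
#' @param h External field (default -2, favoring sparse hub calls).
#' @param tau0,tau1 Non-negative couplings (defaults 0.5).
#' @param u_bar Prior mean of the hub emission mean (default 2).
#' @param a Prior precision scale of the mean (default 1).
#' @param upsilon Inverse-gamma degrees of freedom (default 4).
#' @param d_scale Inverse-gamma scale (default 1).
#' @return An `mrf_hyperparams` list.
#' @export
mrf_hyperparams <- function(h = -2, tau0 = 0.5, tau1 = 0.5, u_bar = 2,
                            a = 1, upsilon = 4, d_scale = 1) {
  stopifnot(is.numeric(h), is.numeric(tau0), is.numeric(tau1),
            a > 0, upsilon > 0, d_scale > 0)
  structure(list(h = h, tau0 = tau0, tau1 = tau1, u_bar = u_bar, a = a,
                 upsilon = upsilon, d_scale = d_scale),
            class = "mrf_hyperparams")
}

# Edge table with degree weights d_i + d_j, d = sqrt(degree).
mrf_edge_weights <- function(graph) {
  A <- graph_adjacency(graph)
  d <- sqrt(rowSums(A))
  el <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  list(i = el[, 1L], j = el[, 2L], w = d[el[, 1L]] + d[el[, 2L]], d = d)
}

#' Log-potential of a hub-state configuration
#'
#' The log of the unnormalized MRF prior:
#' `h * sum I(T_i = 1) + tau0 * sum_edges (d_i + d_j) I(T_i = 0) I(T_j = 0)
#'  + tau1 * sum_edges (d_i + d_j) I(T_i = 1) I(T_j = 1)`,
#' with `d_i = sqrt(degree_i)`. The normalizing function over the `2^n`
#' configurations is not included (see [enumerate_hub_posterior()] for the
#' exact small-n mode).
#'
#' @param T_state Binary vector of length `n`.
#' @param graph Undirected simple `igraph` graph.
#' @param hp An [mrf_hyperparams()] object.
#' @return Numeric scalar.
#' @export
mrf_log_potential <- function(T_state, graph, hp = mrf_hyperparams()) {
  graph <- check_cell_graph(graph)
  n <- igraph::vcount(graph)
  if (length(T_state) != n || !all(T_state %in% c(0, 1))) {
    abort("`T_state` must be a binary vector with one entry per node.")
  }
  ew <- mrf_edge_weights(graph)
  Ti <- T_state[ew$i]
  Tj <- T_state[ew$j]
  hp$h * sum(T_state) +
    hp$tau0 * sum(ew$w * (1 - Ti) * (1 - Tj)) +
    hp$tau1 * sum(ew$w * Ti * Tj)
}

#' Posterior hub inference by Gibbs sampling
#'
#' Systematic-scan Gibbs sampler for the hidden MRF. Each sweep (a) updates
#' every `T_i` from its full conditional, combining the emission density of
#' `omega_i` (standard normal under `T_i = 0`, `N(mu_i, sigma_i^2)` under
#' `T_i = 1`) with the degree-weighted Ising neighbor terms, and (b)
#' redraws `(mu_i, sigma_i^2)` from the conjugate Normal-Inverse-Gamma full
#' conditional (the posterior given `omega_i` when `T_i = 1`, the prior
#' otherwise). Marginals are Monte-Carlo averages of `T` over the retained
#' sweeps; hub calls threshold the marginal at 0.5 (the marginal
#' posterior-mode estimate of the joint argmax).
#'
#' @param omega Numeric evidence vector (from [z_transform()]).
#' @param graph Undirected simple `igraph` graph on the same nodes.
#' @param hp An [mrf_hyperparams()] object.
#' @param n_burnin,n_samples Discarded and retained sweeps (defaults 1000
#'   and 5000).
#' @param seed Integer seed; seeded runs are exactly reproducible.
#' @param fixed_mu,fixed_sigma2 Optional fixed emission parameter vectors;
#'   when both are supplied step (b) is skipped (used for validation
#'   against exact enumeration).
#' @return A `hub_posterior` object: tibble-friendly fields `marginal`
#'   (posterior `P(T_i = 1 | omega)`), `hub_call`, `mu_mean`,
#'   `sigma2_mean`, plus the inputs and sampler settings.
#' @export
gibbs_posterior <- function(omega, graph, hp = mrf_hyperparams(),
                            n_burnin = 1000L, n_samples = 5000L,
                            seed = NULL, fixed_mu = NULL,
                            fixed_sigma2 = NULL) {
  graph <- check_cell_graph(graph)
  n <- igraph::vcount(graph)
  if (length(omega) != n || any(!is.finite(omega))) {
    abort("`omega` must be a finite vector with one entry per node.")
  }
  if (!is_count(n_samples, min = 1L) || !is_count(n_burnin, min = 0L)) {
    abort("`n_burnin` must be >= 0 and `n_samples` >= 1.")
  }
  fixed <- !is.null(fixed_mu) && !is.null(fixed_sigma2)
  if (fixed && (length(fixed_mu) != n || length(fixed_sigma2) != n ||
                any(fixed_sigma2 <= 0))) {
    abort("Fixed emission parameters must give mu and sigma2 > 0 per node.")
  }

  ew <- mrf_edge_weights(graph)
  nbr <- vector("list", n)   # neighbor indices and edge weights per node
  nbw <- vector("list", n)
  for (k in seq_along(ew$i)) {
    i <- ew$i[k]; j <- ew$j[k]
    nbr[[i]] <- c(nbr[[i]], j); nbw[[i]] <- c(nbw[[i]], ew$w[k])
    nbr[[j]] <- c(nbr[[j]], i); nbw[[j]] <- c(nbw[[j]], ew$w[k])
  }
  log_f0 <- dnorm(omega, 0, 1, log = TRUE)

  run <- function() {
    Tv <- rep(0L, n)
    if (fixed) {
      mu <- fixed_mu; s2 <- fixed_sigma2
    } else {
      s2 <- 1 / rgamma(n, hp$upsilon / 2, rate = hp$upsilon * hp$d_scale / 2)
      mu <- rnorm(n, hp$u_bar, sqrt(s2 / hp$a))
    }
    marg <- numeric(n); mu_acc <- numeric(n); s2_acc <- numeric(n)
    total <- n_burnin + n_samples
    for (sweep in seq_len(total)) {
      log_f1 <- dnorm(omega, mu, sqrt(s2), log = TRUE)
      u <- runif(n)
      for (i in seq_len(n)) {
        nb <- nbr[[i]]
        lo <- hp$h + log_f1[i] - log_f0[i]
        if (length(nb)) {
          Tn <- Tv[nb]; w <- nbw[[i]]
          lo <- lo + hp$tau1 * sum(w * Tn) - hp$tau0 * sum(w * (1 - Tn))
        }
        Tv[i] <- if (u[i] < plogis(lo)) 1L else 0L
      }
      if (!fixed) {
        act <- Tv == 1L
        a_n <- ifelse(act, hp$a + 1, hp$a)
        u_n <- ifelse(act, (hp$a * hp$u_bar + omega) / (hp$a + 1), hp$u_bar)
        ups_n <- ifelse(act, hp$upsilon + 1, hp$upsilon)
        scale_n <- hp$upsilon * hp$d_scale +
          ifelse(act, hp$a / (hp$a + 1) * (omega - hp$u_bar)^2, 0)
        s2 <- 1 / rgamma(n, ups_n / 2, rate = scale_n / 2)
        mu <- rnorm(n, u_n, sqrt(s2 / a_n))
      }
      if (sweep > n_burnin) {
        marg <- marg + Tv
        mu_acc <- mu_acc + mu
        s2_acc <- s2_acc + s2
      }
    }
    list(marginal = marg / n_samples, mu_mean = mu_acc / n_samples,
         sigma2_mean = s2_acc / n_samples)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())

  structure(list(
    node_ids = igraph::V(graph)$name,
    omega = omega,
    marginal = setNames(res$marginal, igraph::V(graph)$name),
    hub_call = res$marginal > 0.5,
    mu_mean = res$mu_mean, sigma2_mean = res$sigma2_mean,
    hp = hp, n_burnin = n_burnin, n_samples = n_samples, seed = seed,
    fixed_emission = fixed
  ), class = "hub_posterior")
}

#' @export
print.hub_posterior <- function(x, ...) {
  cat(sprintf("<hub_posterior> %d nodes, %d hub call(s), %d sweeps retained\n",
              length(x$marginal), sum(x$hub_call), x$n_samples))
  invisible(x)
}

#' @describeIn gibbs_posterior Tidy per-node table: `node_id`, `omega`,
#'   `posterior_marginal`, `hub_call`.
#' @param x A `hub_posterior` object.
#' @param ... Unused.
#' @export
tidy.hub_posterior <- function(x, ...) {
  tibble::tibble(
    node_id = x$node_ids,
    omega = unname(x$omega),
    posterior_marginal = unname(x$marginal),
    hub_call = unname(x$hub_call)
  )
}

#' Exact posterior marginals by enumeration (validation mode)
#'
#' Enumerates all `2^n` hub-state configurations and computes the exact
#' posterior marginals under fixed emission parameters, including the MRF
#' normalizing function. Only feasible for small graphs (`n <= 20`); used
#' to validate the Gibbs sampler.
#'
#' @inheritParams gibbs_posterior
#' @param mu,sigma2 Fixed emission parameter vectors.
#' @return Named vector of exact marginals `P(T_i = 1 | omega)`.
#' @export
enumerate_hub_posterior <- function(omega, graph, hp = mrf_hyperparams(),
                                    mu, sigma2) {
  graph <- check_cell_graph(graph)
  n <- igraph::vcount(graph)
  if (n > 20L) abort("Enumeration is limited to n <= 20 nodes.")
  stopifnot(length(omega) == n, length(mu) == n, length(sigma2) == n,
            all(sigma2 > 0))
  ew <- mrf_edge_weights(graph)
  log_f0 <- dnorm(omega, 0, 1, log = TRUE)
  log_f1 <- dnorm(omega, mu, sqrt(sigma2), log = TRUE)
  configs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))  # column k = node k
  lp <- apply(configs, 1L, function(Tv) {
    Ti <- Tv[ew$i]; Tj <- Tv[ew$j]
    hp$h * sum(Tv) +
      hp$tau0 * sum(ew$w * (1 - Ti) * (1 - Tj)) +
      hp$tau1 * sum(ew$w * Ti * Tj) +
      sum(ifelse(Tv == 1, log_f1, log_f0))
  })
  post <- exp(lp - logsumexp(lp))
  setNames(as.vector(crossprod(configs, post)), igraph::V(graph)$name)
}
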