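# Mixture of ERGMs over latent node classes, fitted by a classification EM
# on the pseudolikelihood, with ICL model selection.
#
# Model: each node i carries a latent class Z_i ~ Multinomial(1, alpha).
# Given classes, each dyad (i, j) contributes an ERGM pseudolikelihood term
# under the block-pair parameters theta[Z_i, Z_j]. Diagonal blocks (within a
# class) use the full configured term set; off-diagonal blocks are
# edges-only (Bernoulli): edges between two different subnetworks are taken
# to arise at random, and cross-cluster structure is instead captured
# downstream by the hub MRF layer. The intractable ERGM normalizing
# constant never appears: every likelihood in this module is a
# pseudolikelihood built from change statistics.

# ---- internal fitting context ----------------------------------------------

mixture_context <- function(graph, config) {
  graph <- check_cell_graph(graph)
  A <- graph_adjacency(graph)
  n <- nrow(A)
  dd <- dyad_design(A, config)
  pair_index <- matrix(0L, n, n)
  k <- seq_along(dd$i)
  pair_index[cbind(dd$i, dd$j)] <- k
  pair_index[cbind(dd$j, dd$i)] <- k
  list(graph = graph, A = A, n = n, dd = dd, pair_index = pair_index,
       config = config, names = rownames(A))
}

# Per-dyad log-pseudolikelihood vectors for every ordered block pair (q, l).
# Returns a G x G list matrix of numeric vectors over dyads.
dyad_loglik_table <- function(ctx, theta) {
  G <- length(theta)
  LL <- vector("list", G * G)
  dim(LL) <- c(G, G)
  for (q in seq_len(G)) {
    for (l in seq_len(q)) {
      th <- theta[[q]][[l]]
      eta <- if (length(th) == 1L) {
        rep(unname(th), length(ctx$dd$y))
      } else {
        as.vector(ctx$dd$X %*% th)
      }
      ll <- ctx$dd$y * eta - log1pexp(eta)
      LL[[q, l]] <- ll
      LL[[l, q]] <- ll
    }
  }
  LL
}

# Class score of one node: log alpha_q + sum over partners j of the dyad
# log-pseudolikelihood under (q, z_j). Returns length-G vector.
node_scores <- function(ctx, i, z, log_alpha, LL) {
  G <- length(log_alpha)
  ks <- ctx$pair_index[i, -i]
  zs <- z[-i]
  s <- log_alpha
  for (l in unique(zs)) {
    sel <- ks[zs == l]
    for (q in seq_len(G)) s[q] <- s[q] + sum(LL[[q, l]][sel])
  }
  s
}

# Classification log-pseudolikelihood at hard labels z (each dyad once).
classification_logpl <- function(ctx, z, alpha, LL) {
  la <- log(pmax(alpha, 1e-300))
  ll <- sum(la[z])
  zi <- z[ctx$dd$i]
  zj <- z[ctx$dd$j]
  for (q in seq_len(length(alpha))) {
    for (l in seq_len(q)) {
      sel <- (zi == q & zj == l) | (zi == l & zj == q)
      if (any(sel)) ll <- ll + sum(LL[[q, l]][sel])
    }
  }
  ll
}

# One sweep of sequential responsibility/label updates. Returns updated
# (resp, z); `order` controls the node visit order; when `gamma` is given
# (online mode) alpha is moved by Robbins-Monro steps after each node.
sweep_estep <- function(ctx, resp, z, alpha, LL, order, gamma = NULL,
                        t_offset = 0L) {
  G <- length(alpha)
  for (pos in seq_along(order)) {
    i <- order[pos]
    s <- node_scores(ctx, i, z, log(pmax(alpha, 1e-300)), LL)
    if (all(!is.finite(s))) {
      warn("Degenerate class scores for a node; using a uniform row.")
      r <- rep(1 / G, G)
    } else {
      r <- exp(s - logsumexp(s))
    }
    resp[i, ] <- r
    z[i] <- which.max(r)  # ties break to the lowest class index
    if (!is.null(gamma)) {
      g <- (t_offset + pos)^(-gamma)
      alpha <- alpha + g * (r - alpha)
      alpha <- alpha / sum(alpha)
    }
  }
  list(resp = resp, z = z, alpha = alpha)
}

# M-step parameter updates from soft responsibilities. Diagonal blocks:
# weighted MPLE with dyad weights r_iq * r_jq over the full term set.
# Off-diagonal blocks: edges-only closed form (the weighted MPLE maximizer
# for a single intercept term is the logit of the weighted edge rate).
# Blocks with vanishing effective weight keep their previous parameters.
mstep_params <- function(ctx, resp, prev_theta = NULL) {
  G <- ncol(resp)
  alpha <- colMeans(resp)
  theta <- vector("list", G)
  for (q in seq_len(G)) theta[[q]] <- vector("list", G)
  theta_se <- theta
  ri <- resp[ctx$dd$i, , drop = FALSE]
  rj <- resp[ctx$dd$j, , drop = FALSE]
  # Haldane-Anscombe regularized edges-only rate: the weighted Bernoulli
  # MPLE with half a pseudo-success and pseudo-failure, finite even for
  # complete or empty blocks.
  edge_rate_theta <- function(w) {
    p <- (sum(w * ctx$dd$y) + 0.5) / (sum(w) + 1)
    c(edges = qlogis(min(max(p, 1e-12), 1 - 1e-12)))
  }
  for (q in seq_len(G)) {
    w <- ri[, q] * rj[, q]
    done <- FALSE
    if (sum(w) < 1e-8) {
      # vanishing effective block: freeze at the previous value
      if (!is.null(prev_theta)) {
        warn(sprintf("Block %d has vanishing weight; parameters frozen.", q))
        theta[[q]][[q]] <- prev_theta[[q]][[q]]
        theta_se[[q]][[q]] <- rep(NA_real_, length(theta[[q]][[q]]))
        done <- TRUE
      }
    } else if (sum(w * ctx$dd$y) > 1e-8 && sum(w * (1 - ctx$dd$y)) > 1e-8) {
      fit <- tryCatch(mple_fit(ctx$dd$X, ctx$dd$y, w), error = function(e) NULL)
      if (!is.null(fit) && all(is.finite(fit$coefficients))) {
        theta[[q]][[q]] <- fit$coefficients
        theta_se[[q]][[q]] <- fit$se
        done <- TRUE
      }
    }
    if (!done) {
      # separated block (complete or empty subgraph): regularized
      # edges-only estimate, remaining terms at zero
      th <- setNames(numeric(length(ctx$config$terms)), ctx$config$terms)
      th["edges"] <- edge_rate_theta(w)
      theta[[q]][[q]] <- th
      theta_se[[q]][[q]] <- rep(NA_real_, length(th))
    }
  }
  if (G > 1L) {
    for (q in 2:G) {
      for (l in seq_len(q - 1L)) {
        w <- ri[, q] * rj[, l] + ri[, l] * rj[, q]
        th <- if (sum(w) < 1e-8) {
          if (!is.null(prev_theta)) prev_theta[[q]][[l]] else c(edges = 0)
        } else {
          edge_rate_theta(w)
        }
        theta[[q]][[l]] <- th
        theta[[l]][[q]] <- th
      }
    }
  }
  list(alpha = alpha, theta = theta, theta_se = theta_se)
}

# ---- exported operations ----------------------------------------------------

#' Initial hard partition of a graph
#'
#' Produces one-hot responsibilities to start the EM. `"spectral"` (default)
#' runs spectral clustering on the symmetrically normalized adjacency
#' (k-means on the leading eigenvector rows); `"random"` draws a seeded
#' uniform partition. Empty classes are repaired by moving nodes out of the
#' largest class, so every class is non-empty.
#'
#' @param graph Undirected simple `igraph` graph.
#' @param G Number of classes, `1 <= G <= n`.
#' @param method `"spectral"` or `"random"`.
#' @param seed Integer seed (used by k-means restarts / the random method).
#' @return An `n x G` matrix of one-hot responsibilities.
#' @export
init_partition <- function(graph, G, method = c("spectral", "random"),
                           seed = NULL) {
  graph <- check_cell_graph(graph)
  method <- match.arg(method)
  n <- igraph::vcount(graph)
  if (!is_count(G, min = 1L) || G > n) {
    abort("`G` must be an integer in [1, number of nodes].")
  }
  if (G == 1L) {
    return(matrix(1, n, 1L, dimnames = list(igraph::V(graph)$name, NULL)))
  }
  labels <- if (method == "random") {
    draw <- function() sample.int(G, n, replace = TRUE)
    if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  } else {
    spectral_labels(graph, G, seed)
  }
  # repair empty classes from the largest class
  for (g in seq_len(G)) {
    while (sum(labels == g) == 0L) {
      big <- which.max(tabulate(labels, G))
      labels[which(labels == big)[1L]] <- g
    }
  }
  resp <- matrix(0, n, G, dimnames = list(igraph::V(graph)$name, NULL))
  resp[cbind(seq_len(n), labels)] <- 1
  resp
}

spectral_labels <- function(graph, G, seed = NULL) {
  A <- graph_adjacency(graph)
  n <- nrow(A)
  deg <- rowSums(A)
  dhalf <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  M <- t(A * dhalf) * dhalf  # D^-1/2 A D^-1/2
  ev <- eigen(M, symmetric = TRUE)
  U <- ev$vectors[, seq_len(G), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  U <- U / ifelse(norms > 0, norms, 1)
  km <- function() {
    tryCatch(kmeans(U, centers = G, nstart = 10L)$cluster,
             error = function(e) sample.int(G, n, replace = TRUE))
  }
  if (is.null(seed)) km() else withr::with_seed(as.integer(seed), km())
}

#' One E-step of the mixture-ERGM EM
#'
#' Recomputes soft responsibilities: for each node `i` and class `q`, the
#' responsibility is proportional to `alpha_q` times the exponentiated
#' conditional log-pseudolikelihood of node i's dyads with `Z_i = q` and all
#' other nodes held at their current hard labels. Rows are normalized with a
#' log-sum-exp guard. Nodes are visited in index order and hard labels are
#' updated in place as the sweep proceeds.
#'
#' @param graph Undirected simple `igraph` graph the model was fitted to.
#' @param model A `mixture_ergm` object (see [fit_mixture_ergm()]).
#' @return An `n x G` responsibility matrix with rows summing to 1.
#' @export
e_step <- function(graph, model) {
  stopifnot(inherits(model, "mixture_ergm"))
  ctx <- mixture_context(graph, model$config)
  LL <- dyad_loglik_table(ctx, model$theta)
  st <- sweep_estep(ctx, model$responsibilities, model$labels, model$alpha,
                    LL, order = seq_len(ctx$n))
  rownames(st$resp) <- ctx$names
  st$resp
}

#' One M-step of the mixture-ERGM EM
#'
#' Updates mixing weights as responsibility column means and refits the
#' block-pair ERGM parameters by soft-weighted maximum pseudolikelihood:
#' diagonal blocks use dyad weights `r_iq * r_jq` over the full term set,
#' off-diagonal blocks an edges-only Bernoulli rate. Blocks whose effective
#' weight vanishes keep `prev_theta` with a warning.
#'
#' @param graph Undirected simple `igraph` graph.
#' @param responsibilities `n x G` matrix with non-negative rows summing to 1.
#' @param config A [stat_config()].
#' @param prev_theta Optional previous block parameters for freezing.
#' @return List with `alpha` and `theta` (G x G list of coefficient vectors).
#' @export
m_step <- function(graph, responsibilities, config = stat_config(),
                   prev_theta = NULL) {
  ctx <- mixture_context(graph, config)
  if (!is.matrix(responsibilities) || nrow(responsibilities) != ctx$n) {
    abort("`responsibilities` must be an n x G matrix.")
  }
  if (any(responsibilities < 0) ||
      max(abs(rowSums(responsibilities) - 1)) > 1e-8) {
    abort("Responsibility rows must be non-negative and sum to 1.")
  }
  out <- mstep_params(ctx, responsibilities, prev_theta)
  out[c("alpha", "theta")]
}

#' Fit a mixture of ERGMs by pseudolikelihood EM
#'
#' Alternates responsibility updates ([e_step()]) and soft-weighted
#' pseudolikelihood M-steps ([m_step()]) until the classification
#' log-pseudolikelihood changes by less than `tol` (relative) or `max_iter`
#' is reached. In online mode, nodes are visited in a seeded random order
#' and the mixing weights follow Robbins-Monro steps
#' `gamma_t = t^-step_size_exponent`; block parameters are refreshed after
#' each sweep. With several restarts, the first uses the spectral
#' initialization and the rest random partitions; the best final objective
#' wins. Final hard labels are the row-wise argmax of the responsibilities,
#' ties broken toward the lowest class index.
#'
#' @param graph Undirected simple `igraph` graph over cells.
#' @param G Number of latent classes (`G = 1` reduces to [fit_mple()]).
#' @param config A [stat_config()] for the diagonal (within-class) blocks.
#' @param max_iter,tol EM stopping rule (relative change of the objective).
#' @param n_restarts Number of initializations.
#' @param seed Integer seed controlling initialization and node order.
#' @param online Use the online (Robbins-Monro) variant.
#' @param step_size_exponent Online step-size exponent in (0.5, 1].
#' @param init Initialization method for the first restart.
#' @return A `mixture_ergm` object: `alpha`, `theta` (G x G list),
#'   `responsibilities`, `labels`, `logpl_trace`, `L_C` (final
#'   classification log-pseudolikelihood), `converged`, `config`, `n`,
#'   `node_ids`.
#' @examples
#' sim <- simulate_mixture_network(n = 30, alpha = c(.5, .5),
#'   theta_within = list(c(edges = 0.5), c(edges = 0.5)),
#'   theta_between = -2.5, config = stat_config("edges"), seed = 1)
#' fit <- fit_mixture_ergm(sim$graph, G = 2, config = stat_config("edges"),
#'                         seed = 1)
#' fit$alpha
#' @export
fit_mixture_ergm <- function(graph, G, config = stat_config(),
                             max_iter = 50L, tol = 1e-6, n_restarts = 1L,
                             seed = NULL, online = FALSE,
                             step_size_exponent = 0.7,
                             init = c("spectral", "random")) {
  graph <- check_cell_graph(graph)
  init <- match.arg(init)
  if (!is_count(G, min = 1L)) abort("`G` must be a positive integer.")
  if (online && (step_size_exponent <= 0.5 || step_size_exponent > 1)) {
    abort("`step_size_exponent` must lie in (0.5, 1].")
  }
  n <- igraph::vcount(graph)
  if (G > n) abort("`G` cannot exceed the number of nodes.")

  if (G == 1L) {
    # exact reduction: the whole-graph MPLE is the G = 1 mixture
    fit <- fit_mple(graph, config)
    theta <- list(list(fit$coefficients))
    resp <- matrix(1, n, 1L, dimnames = list(igraph::V(graph)$name, NULL))
    out <- structure(list(
      G = 1L, alpha = 1, theta = theta, theta_se = list(list(fit$se)),
      responsibilities = resp, labels = rep(1L, n),
      logpl_trace = fit$logpl, L_C = fit$logpl, converged = fit$converged,
      n_iter = 1L, config = config, n = n,
      node_ids = igraph::V(graph)$name, online = online, seed = seed
    ), class = "mixture_ergm")
    return(out)
  }

  ctx <- mixture_context(graph, config)
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    rs_seed <- if (is.null(seed)) NULL else derive_seed(seed, "restart") + rs
    method <- if (rs == 1L) init else "random"
    resp0 <- init_partition(graph, G, method = method, seed = rs_seed)
    fit <- tryCatch(
      em_run(ctx, resp0, max_iter, tol, online, step_size_exponent, rs_seed),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$L_C > best$L_C) best <- fit
  }
  if (is.null(best)) abort("All EM restarts failed; try a different G or seed.")
  structure(c(best, list(config = config, n = n, node_ids = ctx$names,
                         G = G, online = online, seed = seed)),
            class = "mixture_ergm")
}

em_run <- function(ctx, resp, max_iter, tol, online, kappa, seed) {
  n <- ctx$n
  G <- ncol(resp)
  z <- max.col(resp, ties.method = "first")
  par <- mstep_params(ctx, resp, prev_theta = NULL)
  trace <- numeric(0)
  L_prev <- -Inf
  converged <- FALSE
  t_global <- 0L
  for (it in seq_len(max_iter)) {
    LL <- dyad_loglik_table(ctx, par$theta)
    ord <- if (online) {
      s <- if (is.null(seed)) NULL else derive_seed(seed, "order") + it
      if (is.null(s)) sample.int(n) else withr::with_seed(s, sample.int(n))
    } else {
      seq_len(n)
    }
    st <- sweep_estep(ctx, resp, z, par$alpha, LL,
                      order = ord,
                      gamma = if (online) kappa else NULL,
                      t_offset = t_global)
    t_global <- t_global + n
    resp <- st$resp
    z <- st$z
    # Classification EM: the M-step weights are the products of the hard
    # one-hot indicators Z, so (E, M) is coordinate ascent on the
    # classification log-pseudolikelihood and the trace is non-decreasing.
    hard <- matrix(0, n, G)
    hard[cbind(seq_len(n), z)] <- 1
    par2 <- mstep_params(ctx, hard, prev_theta = par$theta)
    if (online) par2$alpha <- st$alpha  # Robbins-Monro running average
    par <- par2
    LL <- dyad_loglik_table(ctx, par$theta)
    L <- classification_logpl(ctx, z, par$alpha, LL)
    trace <- c(trace, L)
    if (is.finite(L_prev) &&
        abs(L - L_prev) < tol * (abs(L_prev) + 1e-12)) {
      converged <- TRUE
      L_prev <- L
      break
    }
    L_prev <- L
  }
  rownames(resp) <- ctx$names
  list(alpha = par$alpha, theta = par$theta, theta_se = par$theta_se,
       responsibilities = resp, labels = z, logpl_trace = trace,
       L_C = L_prev, converged = converged, n_iter = length(trace))
}

#' @export
print.mixture_ergm <- function(x, ...) {
  cat(sprintf(
    "<mixture_ergm> G = %d, n = %d, L_C = %.3f (%s after %d iteration%s)\n",
    x$G, x$n, x$L_C, if (x$converged) "converged" else "not converged",
    x$n_iter, if (x$n_iter == 1L) "" else "s"))
  cat("alpha:", paste(sprintf("%.3f", x$alpha), collapse = " "), "\n")
  invisible(x)
}

#' Integrated classification likelihood value
#'
#' `ICL(G) = -2 L_C + (G * M_stats + G - 1) * log(n)` where `L_C` is the
#' classification log-(pseudo)likelihood at the hard labels, `M_stats` the
#' number of summary statistics in the model and `n` the number of nodes.
#' Written as a penalized deviance, so smaller is better; minimizing this
#' form is the same model choice as maximizing the equivalent penalized
#' classification likelihood.
#'
#' @param L_C Classification log-(pseudo)likelihood.
#' @param G Number of classes.
#' @param M_stats Number of summary statistics.
#' @param n Number of nodes.
#' @return The ICL value (numeric scalar).
#' @examples
#' icl_value(L_C = -100, G = 3, M_stats = 4, n = 50)
#' @export
icl_value <- function(L_C, G, M_stats, n) {
  stopifnot(is.numeric(L_C), is_count(G, 1L), is_count(M_stats, 1L),
            is.numeric(n), n >= 1)
  -2 * L_C + (G * M_stats + G - 1) * log(n)
}

#' ICL record of a fitted mixture-ERGM
#'
#' @param model A fitted `mixture_ergm` object.
#' @param graph Unused; accepted so the call mirrors the fitting interface.
#' @return A one-row tibble with `G`, `L_C`, `M_stats`, `n`, `icl`.
#' @export
icl <- function(model, graph = NULL) {
  if (!inherits(model, "mixture_ergm") || is.null(model$L_C)) {
    abort("`model` must be a fitted mixture_ergm object.")
  }
  M_stats <- length(model$config$terms)
  tibble::tibble(
    G = model$G, L_C = model$L_C, M_stats = M_stats, n = model$n,
    icl = icl_value(model$L_C, model$G, M_stats, model$n)
  )
}

#' Choose the number of clusters by ICL
#'
#' Fits the mixture for every `G` in `G_range` and returns the full ICL
#' table together with the model minimizing the penalized-deviance ICL (the
#' same optimum as maximizing the equivalent penalized classification
#' likelihood). The table is kept so the choice can be audited and
#' overridden.
#'
#' @param graph Undirected simple `igraph` graph.
#' @param G_range Integer vector of candidate class counts.
#' @param ... Passed to [fit_mixture_ergm()] (config, seed, EM options).
#' @return An `icl_table` object: list with `table` (tibble, one row per G),
#'   `best_G`, `best_model`, `models`.
#' @export
select_G <- function(graph, G_range = 2:6, ...) {
  graph <- check_cell_graph(graph)
  G_range <- sort(unique(as.integer(G_range)))
  if (length(G_range) == 0L) abort("`G_range` must be non-empty.")
  if (min(G_range) < 1L || max(G_range) > igraph::vcount(graph)) {
    abort("`G_range` must lie within [1, number of nodes].")
  }
  models <- vector("list", length(G_range))
  rows <- vector("list", length(G_range))
  for (k in seq_along(G_range)) {
    fit <- fit_mixture_ergm(graph, G = G_range[k], ...)
    models[[k]] <- fit
    rows[[k]] <- dplyr::mutate(icl(fit), converged = fit$converged)
  }
  table <- dplyr::bind_rows(rows)
  best <- which.min(table$icl)
  structure(list(table = table, best_G = G_range[best],
                 best_model = models[[best]], models = models),
            class = "icl_table")
}

#' @export
print.icl_table <- function(x, ...) {
  cat(sprintf("<icl_table> best G = %d\n", x$best_G))
  print(x$table)
  invisible(x)
}

#' Cluster assignments of a fitted mixture-ERGM
#'
#' @param model A fitted `mixture_ergm` object.
#' @return A tibble with `cell_id`, `cluster` and `max_responsibility`.
#' @export
cluster_assignments <- function(model) {
  stopifnot(inherits(model, "mixture_ergm"))
  tibble::tibble(
    cell_id = model$node_ids,
    cluster = as.integer(model$labels),
    max_responsibility = model$responsibilities[
      cbind(seq_len(model$n), model$labels)]
  )
}

#' @describeIn fit_mixture_ergm Tidy the block-pair coefficients: one row
#'   per (block_l, block_q, term).
#' @param x,object A `mixture_ergm` fit.
#' @param ... Unused.
#' @export
tidy.mixture_ergm <- function(x, ...) {
  rows <- list()
  for (q in seq_len(x$G)) {
    for (l in seq_len(q)) {
      th <- x$theta[[q]][[l]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        block_l = l, block_q = q, term = names(th), estimate = unname(th)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' @describeIn fit_mixture_ergm One-row fit summary.
#' @export
glance.mixture_ergm <- function(x, ...) {
  dplyr::mutate(icl(x), converged = x$converged, n_iter = x$n_iter)
}
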