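# Mixture-of-ERGMs EM, ICL model selection, and their reductions.

two_clique_graph <- function(k = 6) {
  g <- igraph::disjoint_union(igraph::make_full_graph(k),
                              igraph::make_full_graph(k))
  igraph::V(g)$name <- paste0("v", seq_len(2 * k))
  g
}

test_that("init_partition covers trivial, spectral and seeded-random cases", {
  g <- two_clique_graph(6)
  r1 <- init_partition(g, 1)
  expect_equal(dim(r1), c(12, 1))
  expect_true(all(r1 == 1))

  # two disconnected cliques: spectral partition equals the components
  r2 <- init_partition(g, 2, method = "spectral", seed = 1)
  lab <- max.col(r2)
  comp <- igraph::components(g)$membership
  expect_equal(ari(lab, comp), 1)

  ra <- init_partition(g, 3, method = "random", seed = 9)
  rb <- init_partition(g, 3, method = "random", seed = 9)
  expect_identical(ra, rb)
  expect_true(all(colSums(ra) >= 1))  # no empty class
  expect_error(init_partition(g, 13), "G")
})

test_that("e_step responsibilities are normalized, label-symmetric and block-faithful", {
  # two strongly separated Bernoulli blocks
  sim <- simulate_mixture_network(
    n = 40, alpha = c(0.5, 0.5),
    theta_within = list(c(edges = qlogis(0.5)), c(edges = qlogis(0.5))),
    theta_between = qlogis(0.02), config = stat_config("edges"), seed = 22)
  fit <- suppressWarnings(fit_mixture_ergm(sim$graph, G = 2,
                                           config = stat_config("edges"),
                                           seed = 2))
  resp <- e_step(sim$graph, fit)
  expect_equal(unname(rowSums(resp)), rep(1, 40), tolerance = 1e-10)
  # well-separated blocks: confident assignments agreeing with truth
  expect_gt(min(apply(resp, 1, max)), 0.99)
  expect_equal(ari(max.col(resp), sim$true_labels), 1)

  # fully exchangeable model (uniform alpha, one common edges-only theta
  # for every block pair): class scores tie, rows become uniform
  sym <- fit
  sym$alpha <- c(0.5, 0.5)
  for (q in 1:2) for (l in 1:2) sym$theta[[q]][[l]] <- c(edges = -1)
  rs <- e_step(sim$graph, sym)
  expect_equal(rs, matrix(0.5, 40, 2, dimnames = dimnames(rs)),
               tolerance = 1e-9)

  # G = 1: all responsibilities exactly 1
  fit1 <- fit_mixture_ergm(sim$graph, G = 1, config = stat_config("edges"))
  expect_true(all(e_step(sim$graph, fit1) == 1))
})

test_that("e_step is equivariant under permuting the class labels", {
  sim <- simulate_mixture_network(n = 36, seed = 31)
  fit <- suppressWarnings(fit_mixture_ergm(sim$graph, G = 3, seed = 3))
  perm <- c(2, 3, 1)
  pfit <- fit
  pfit$alpha <- fit$alpha[order(perm)]
  for (q in 1:3) for (l in 1:3) {
    pfit$theta[[perm[q]]][[perm[l]]] <- fit$theta[[q]][[l]]
  }
  pfit$labels <- perm[fit$labels]
  pfit$responsibilities <- fit$responsibilities[, order(perm), drop = FALSE]
  r0 <- e_step(sim$graph, fit)
  r1 <- e_step(sim$graph, pfit)
  expect_equal(r1, r0[, order(perm), drop = FALSE], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("m_step recovers mixing weights and block Bernoulli rates", {
  sim <- simulate_mixture_network(
    n = 40, alpha = c(0.5, 0.5),
    theta_within = list(c(edges = qlogis(0.4)), c(edges = qlogis(0.4))),
    theta_between = qlogis(0.05), config = stat_config("edges"), seed = 8)
  g <- sim$graph
  # hard one-hot responsibilities with equal class sizes -> alpha = (.5, .5)
  lab <- rep(1:2, each = 20)
  resp <- matrix(0, 40, 2)
  resp[cbind(1:40, lab)] <- 1
  ms <- m_step(g, resp, config = stat_config("edges"))
  expect_equal(ms$alpha, c(0.5, 0.5))

  # within-block Bernoulli(p): block theta_edges near logit(p)
  sim2 <- simulate_mixture_network(
    n = 50, alpha = c(0.6, 0.4),
    theta_within = list(c(edges = qlogis(0.35)), c(edges = qlogis(0.35))),
    theta_between = qlogis(0.05), config = stat_config("edges"), seed = 9)
  hard <- matrix(0, 50, 2)
  hard[cbind(1:50, sim2$true_labels)] <- 1
  ms2 <- m_step(sim2$graph, hard, config = stat_config("edges"))
  for (q in 1:2) {
    idx <- which(sim2$true_labels == q)
    sub <- igraph::induced_subgraph(sim2$graph, idx)
    fit_q <- fit_mple(sub, stat_config("edges"))
    expect_lt(abs(ms2$theta[[q]][[q]][["edges"]] - qlogis(0.35)),
              3 * fit_q$se[["edges"]])
  }

  # G = 1 m_step equals the plain whole-graph MPLE
  ones <- matrix(1, 50, 1)
  ms1 <- m_step(sim2$graph, ones, config = stat_config("edges"))
  plain <- fit_mple(sim2$graph, stat_config("edges"))
  expect_equal(ms1$theta[[1]][[1]], coef(plain), tolerance = 1e-10)
})

test_that("G = 1 fit reduces bitwise to the whole-graph MPLE", {
  g <- random_graph(40, 0.2, seed = 15)
  cfg <- stat_config(c("edges", "two_stars"), decay = 0.5)
  fit1 <- fit_mixture_ergm(g, G = 1, config = cfg)
  plain <- fit_mple(g, cfg)
  expect_identical(fit1$theta[[1]][[1]], plain$coefficients)
  expect_identical(fit1$L_C, plain$logpl)
})

test_that("EM recovers a separated 3-block mixture with a monotone objective", {
  sim <- simulate_mixture_network(n = 60, seed = 11)
  fit <- suppressWarnings(fit_mixture_ergm(sim$graph, G = 3, seed = 7))
  expect_gte(ari(fit$labels, sim$true_labels), 0.8)
  emp <- as.vector(table(factor(sim$true_labels, levels = 1:3))) / 60
  expect_lt(max(abs(sort(fit$alpha) - sort(emp))), 0.1)
  expect_equal(unname(rowSums(fit$responsibilities)), rep(1, 60),
               tolerance = 1e-10)
  # batch classification EM: objective non-decreasing up to numerical slack
  expect_true(all(diff(fit$logpl_trace) > -1e-8))
})

test_that("online EM with Robbins-Monro steps also recovers the blocks", {
  sim <- simulate_mixture_network(n = 60, seed = 12)
  fit <- suppressWarnings(
    fit_mixture_ergm(sim$graph, G = 3, seed = 4, online = TRUE,
                     step_size_exponent = 0.7))
  expect_gte(ari(fit$labels, sim$true_labels), 0.8)
  expect_error(
    fit_mixture_ergm(sim$graph, G = 3, online = TRUE,
                     step_size_exponent = 0.4),
    "step_size_exponent")
})

test_that("fits are reproducible given a seed", {
  sim <- simulate_mixture_network(n = 45, seed = 14)
  f1 <- suppressWarnings(fit_mixture_ergm(sim$graph, G = 3, seed = 5,
                                          n_restarts = 2))
  f2 <- suppressWarnings(fit_mixture_ergm(sim$graph, G = 3, seed = 5,
                                          n_restarts = 2))
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$theta, f2$theta)
})

test_that("ICL follows its defining formula and is monotone in n", {
  expect_equal(icl_value(L_C = -100, G = 3, M_stats = 4, n = 50),
               200 + 14 * log(50), tolerance = 1e-12)
  expect_equal(icl_value(L_C = 0, G = 1, M_stats = 1, n = exp(1)), 1,
               tolerance = 1e-12)
  ns <- c(10, 50, 200, 1000)
  vals <- vapply(ns, function(n) icl_value(-100, 3, 4, n), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the ICL table satisfies the record invariant row by row", {
  sim <- simulate_mixture_network(n = 36, seed = 16)
  sel <- suppressWarnings(select_G(sim$graph, 2:4, seed = 6))
  tab <- sel$table
  expect_equal(tab$icl,
               -2 * tab$L_C + (tab$G * tab$M_stats + tab$G - 1) * log(tab$n),
               tolerance = 1e-12)
  expect_identical(tab$G, 2:4)
})

test_that("model selection finds the generating structure", {
  # separated 3-block mixture: ICL picks G = 3
  sim <- simulate_mixture_network(n = 60, seed = 11)
  sel <- suppressWarnings(select_G(sim$graph, 2:5, seed = 7))
  expect_equal(sel$best_G, 3L)
  # a single Bernoulli graph has no block structure: ICL picks G = 1
  g <- random_graph(50, 0.15, seed = 91)
  sel1 <- suppressWarnings(select_G(g, 1:3, config = stat_config("edges"),
                                    seed = 8))
  expect_equal(sel1$best_G, 1L)
  expect_error(select_G(g, integer(0)), "non-empty")
})

test_that("tidy, glance and assignments expose the fitted mixture", {
  sim <- simulate_mixture_network(n = 36, seed = 19)
  fit <- suppressWarnings(fit_mixture_ergm(sim$graph, G = 2, seed = 2))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("block_l", "block_q", "term", "estimate") %in% names(td)))
  # diagonal blocks carry the full term set, off-diagonal edges only
  expect_equal(sum(td$block_l == 1 & td$block_q == 2), 1L)
  gl <- glance(fit)
  expect_equal(gl$G, 2L)
  expect_equal(gl$icl, icl_value(fit$L_C, 2L, 4L, 36L))
  ca <- cluster_assignments(fit)
  expect_equal(nrow(ca), 36L)
  expect_true(all(ca$cluster %in% 1:2))
  expect_true(all(ca$max_responsibility >= 0.5 - 1e-12))
})
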