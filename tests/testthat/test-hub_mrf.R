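# Hub values, z-transform, MRF potential and Gibbs posterior inference.

test_that("hub values follow n_i / degree_i with the isolated-node default", {
  # star center with neighbors in 2 clusters among degree 4
  g <- star_graph(5)
  hv <- hub_values(g, c(9, 1, 1, 2, 2))  # labels need not be 1..K
  expect_equal(unname(hv["v1"]), 2 / 4)
  # leaves see only the center's cluster: hv = 1 / degree = 1
  expect_equal(unname(hv["v2"]), 1)

  # all neighbors in one cluster, degree d -> 1/d
  g2 <- star_graph(6)
  hv2 <- hub_values(g2, c(1, 2, 2, 2, 2, 2))
  expect_equal(unname(hv2["v1"]), 1 / 5)

  # isolated node gets hv = 1 (no hub evidence)
  g3 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g3)$name <- c("a", "b", "c")
  expect_equal(unname(hub_values(g3, c(1, 2, 3))), rep(1, 3))

  expect_error(hub_values(star_graph(4), c(a = 1)), "label")
})

test_that("z-transform is the upper-half normal quantile, clamped and monotone", {
  expect_equal(z_transform(1), 0)
  expect_equal(z_transform(0.5), qnorm(0.75), tolerance = 1e-12)
  expect_equal(z_transform(0.5), 0.6744898, tolerance = 1e-7)
  expect_true(is.finite(z_transform(1e-12)))
  expect_error(z_transform(0), "0, 1")
  expect_error(z_transform(1.2), "0, 1")
  hv <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(z_transform(hv)) < 0))
  # inverted direction scores many-cluster connectors high
  expect_gt(z_transform(0.9, invert = TRUE), z_transform(0.2, invert = TRUE))
})

test_that("the log-potential matches hand arithmetic", {
  g <- path_graph(2)  # single edge, degrees (1, 1), d_i + d_j = 2
  hp <- mrf_hyperparams(h = 1, tau0 = 7, tau1 = 2)
  expect_equal(mrf_log_potential(c(1, 1), g, hp), 1 * 2 + 2 * 2)
  # tau couplings off: potential is h times the number of active nodes
  hp0 <- mrf_hyperparams(h = 1.5, tau0 = 0, tau1 = 0)
  g2 <- random_graph(8, 0.4, seed = 2)
  Tv <- c(1, 0, 1, 1, 0, 0, 0, 1)
  expect_equal(mrf_log_potential(Tv, g2, hp0), 1.5 * 4)
  # all-zero state: tau0 times the degree-weighted edge sum
  hpz <- mrf_hyperparams(h = 3, tau0 = 0.5, tau1 = 9)
  d <- sqrt(igraph::degree(g2))
  el <- igraph::as_edgelist(g2, names = FALSE)
  expect_equal(mrf_log_potential(rep(0, 8), g2, hpz),
               0.5 * sum(d[el[, 1]] + d[el[, 2]]))
  expect_error(mrf_log_potential(c(1, 0), g2, hpz), "one entry per node")
})

test_that("Gibbs marginals agree with exact enumeration on a small graph", {
  g <- path_graph(5)
  omega <- c(0.2, 3.5, 1.0, 4.2, -0.5)
  hp <- mrf_hyperparams()
  mu <- rep(3, 5)
  s2 <- rep(1, 5)
  exact <- enumerate_hub_posterior(omega, g, hp, mu, s2)
  post <- gibbs_posterior(omega, g, hp, n_burnin = 1000, n_samples = 20000,
                          seed = 9, fixed_mu = mu, fixed_sigma2 = s2)
  expect_lt(max(abs(post$marginal - exact)), 0.02)
})

test_that("decoupled field factorizes over nodes (quadrature oracle)", {
  g <- random_graph(6, 0.5, seed = 3)
  omega <- c(0.2, 3.5, 1.0, 4.2, -0.5, 2.0)
  hp <- mrf_hyperparams(tau0 = 0, tau1 = 0)
  # marginal hub emission: N(u_bar, s2 * (1 + 1/a)) integrated over the
  # inverse-gamma law of s2 by 1-D quadrature
  m1 <- vapply(omega, function(w) {
    integrate(function(s2) {
      dnorm(w, hp$u_bar, sqrt(s2 * (1 + 1 / hp$a))) *
        (hp$upsilon * hp$d_scale / 2)^(hp$upsilon / 2) / gamma(hp$upsilon / 2) *
        s2^(-hp$upsilon / 2 - 1) * exp(-hp$upsilon * hp$d_scale / (2 * s2))
    }, 0, Inf)$value
  }, numeric(1))
  factorized <- plogis(hp$h + log(m1) - dnorm(omega, log = TRUE))
  post <- gibbs_posterior(omega, g, hp, n_burnin = 1000, n_samples = 20000,
                          seed = 5)
  expect_lt(max(abs(post$marginal - factorized)), 0.02)
})

test_that("a strongly negative field silences flat evidence", {
  g <- random_graph(10, 0.3, seed = 6)
  post <- gibbs_posterior(rep(0, 10), g, mrf_hyperparams(h = -20),
                          n_burnin = 200, n_samples = 2000, seed = 2)
  expect_true(all(post$marginal < 0.01))
})

test_that("marginals are monotone in the evidence and in tau1 (by enumeration)", {
  g <- path_graph(4)
  hp <- mrf_hyperparams(tau0 = 0.2, tau1 = 0.2)
  mu <- rep(2, 4)
  s2 <- rep(1, 4)
  base <- c(0.5, 0.5, 0.5, 0.5)
  marg2 <- vapply(seq(0, 4, by = 0.5), function(w) {
    om <- base
    om[2] <- w
    enumerate_hub_posterior(om, g, hp, mu, s2)[[2]]
  }, numeric(1))
  expect_true(all(diff(marg2) > 0))

  # raising tau1 never lowers the posterior mass of linked hub pairs
  omega <- c(2.5, 2.0, 0.3, 1.5)
  pair_mass <- vapply(c(0, 0.3, 0.8, 1.5), function(t1) {
    hp1 <- mrf_hyperparams(tau0 = 0.2, tau1 = t1)
    configs <- as.matrix(expand.grid(rep(list(c(0, 1)), 4)))
    ew <- igraph::as_edgelist(g, names = FALSE)
    lp <- apply(configs, 1, function(Tv) {
      mrf_log_potential(Tv, g, hp1) +
        sum(ifelse(Tv == 1, dnorm(omega, mu, sqrt(s2), log = TRUE),
                   dnorm(omega, log = TRUE)))
    })
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    linked <- apply(configs, 1, function(Tv) {
      any(Tv[ew[, 1]] == 1 & Tv[ew[, 2]] == 1)
    })
    sum(p[linked])
  }, numeric(1))
  expect_true(all(diff(pair_mass) >= -1e-12))
})

test_that("seeded Gibbs runs are bitwise reproducible", {
  g <- random_graph(12, 0.3, seed = 7)
  om <- withr::with_seed(1, rnorm(12, 1, 1.5))
  p1 <- gibbs_posterior(om, g, n_burnin = 100, n_samples = 500, seed = 42)
  p2 <- gibbs_posterior(om, g, n_burnin = 100, n_samples = 500, seed = 42)
  expect_identical(p1$marginal, p2$marginal)
  expect_identical(p1$mu_mean, p2$mu_mean)
  td <- tidy(p1)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 12)
})

test_that("planted hubs are recovered by the posterior ranking", {
  sim <- simulate_mixture_network(n = 80, seed = 42)
  ph <- plant_hub_field(sim$graph, frac_hubs = 0.15, mu_star = 4,
                        sigma_star = 1, seed = 7)
  # matched analysis for an iid planted field: no spatial coupling
  post <- gibbs_posterior(ph$omega, sim$graph,
                          mrf_hyperparams(tau0 = 0, tau1 = 0),
                          n_burnin = 300, n_samples = 1500, seed = 11)
  expect_gt(auc_score(ph$T_true, post$marginal), 0.95)
})
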