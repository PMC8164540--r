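# ERGM kernel: summary statistics, change statistics, sampler, MPLE.

test_that("summary statistics match complete enumeration on canonical graphs", {
  cfg <- stat_config(c("edges", "two_stars", "triangles"))
  expect_equal(network_statistics(k3_graph(), cfg),
               c(edges = 3, two_stars = 3, triangles = 1))
  expect_equal(network_statistics(c4_graph(), cfg),
               c(edges = 4, two_stars = 4, triangles = 0))
  # star on 5 nodes: 4 edges, choose(4, 2) two-stars at the hub, no triangles
  expect_equal(network_statistics(star_graph(5), cfg),
               c(edges = 4, two_stars = 6, triangles = 0))
})

test_that("gwesp on a triangle equals 3 for any decay (each edge has one shared partner)", {
  for (lam in c(0.25, 0.5, 1.3)) {
    s <- network_statistics(k3_graph(), stat_config(c("edges", "gwesp"),
                                                    decay = lam))
    expect_equal(unname(s["gwesp"]), 3 * exp(lam) * (1 - (1 - exp(-lam))),
                 tolerance = 1e-12)
    expect_equal(unname(s["gwesp"]), 3, tolerance = 1e-12)
  }
})

test_that("gw terms agree with direct summation over the degree / shared-partner histograms", {
  g <- random_graph(25, 0.25, seed = 8)
  lam <- 0.7
  s <- network_statistics(g, stat_config(c("edges", "gw_degree", "gwesp"),
                                         decay = lam))
  deg <- igraph::degree(g)
  Dk <- table(deg[deg > 0])
  direct_gwd <- exp(lam) * sum((1 - (1 - exp(-lam))^as.numeric(names(Dk))) * Dk)
  expect_equal(unname(s["gw_degree"]), direct_gwd, tolerance = 1e-12)

  el <- igraph::as_edgelist(g, names = FALSE)
  sp <- apply(el, 1, function(e) {
    length(intersect(igraph::neighbors(g, e[1]), igraph::neighbors(g, e[2])))
  })
  EPk <- table(sp)
  direct_gwesp <- exp(lam) *
    sum((1 - (1 - exp(-lam))^as.numeric(names(EPk))) * EPk)
  expect_equal(unname(s["gwesp"]), direct_gwesp, tolerance = 1e-12)

  # limits of the geometric weighting: w(k) -> k as decay grows (sum of
  # degrees), w(k) -> 1 as decay vanishes (number of non-isolated nodes)
  big <- network_statistics(g, stat_config(c("edges", "gw_degree"), decay = 20))
  expect_equal(unname(big["gw_degree"]), sum(deg), tolerance = 1e-6)
  tiny <- network_statistics(g, stat_config(c("edges", "gw_degree"),
                                            decay = 1e-8))
  expect_equal(unname(tiny["gw_degree"]), sum(deg > 0), tolerance = 1e-5)
})

test_that("statistics are invariant under node relabeling", {
  cfg <- all_terms_config()
  g <- random_graph(15, 0.3, seed = 4)
  perm <- withr::with_seed(2, sample(15))
  g2 <- igraph::permute(g, perm)
  expect_equal(network_statistics(g, cfg), network_statistics(g2, cfg))
})

test_that("change statistics match hand-worked small cases", {
  cfg <- stat_config(c("edges", "two_stars", "triangles"))
  empty3 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(empty3)$name <- paste0("v", 1:3)
  expect_equal(change_statistics(empty3, c("v1", "v2"), cfg),
               c(edges = 1, two_stars = 0, triangles = 0))
  expect_equal(change_statistics(path_graph(3), c("v1", "v3"), cfg),
               c(edges = 1, two_stars = 2, triangles = 1))
  expect_error(change_statistics(path_graph(3), c("v1", "v1"), cfg),
               "Self-loop")
})

test_that("change statistics equal the brute-force recompute difference exactly", {
  cfg <- all_terms_config(decay = 0.6)
  for (rep in 1:8) {
    g <- random_graph(n = 10 + 2 * rep, p = 0.25, seed = 50 + rep)
    n <- igraph::vcount(g)
    dyads <- withr::with_seed(rep, replicate(5, sample(n, 2), simplify = FALSE))
    for (d in dyads) {
      nm <- igraph::V(g)$name[d]
      expect_equal(change_statistics(g, nm, cfg), brute_change(g, nm, cfg),
                   tolerance = 1e-12)
    }
  }
})

test_that("sampler is seeded-reproducible and respects degenerate limits", {
  cfg <- stat_config("edges")
  g1 <- sample_ergm(20, qlogis(0.3), cfg, seed = 5)
  g2 <- sample_ergm(20, qlogis(0.3), cfg, seed = 5)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  # strongly negative edge coefficient: empty graph
  expect_equal(igraph::ecount(sample_ergm(30, -20, cfg, seed = 1)), 0)
  expect_error(sample_ergm(10, NaN, cfg), "finite")
  expect_error(sample_ergm(1, 0, cfg), "n")
})

test_that("edges-only sampler hits its Bernoulli density", {
  # edges-only ERGM is iid Bernoulli(plogis(theta)) over dyads
  dens <- vapply(1:20, function(s) {
    igraph::edge_density(sample_ergm(30, qlogis(0.15), stat_config("edges"),
                                     seed = 200 + s))
  }, numeric(1))
  mc_se <- sqrt(0.15 * 0.85 / choose(30, 2) / 20)
  expect_lt(abs(mean(dens) - 0.15), 3 * mc_se)
})

test_that("MPLE recovers Bernoulli-graph parameters and flags separation", {
  g <- random_graph(200, 0.1, seed = 77)
  fit <- fit_mple(g, stat_config("edges"))
  expect_lt(abs(coef(fit)[["edges"]] - qlogis(0.1)), 3 * fit$se[["edges"]])

  # half of all dyads present at random: logit(0.5) = 0
  g2 <- random_graph(120, 0.5, seed = 78)
  fit2 <- fit_mple(g2, stat_config("edges"))
  expect_lt(abs(coef(fit2)[["edges"]]), 3 * fit2$se[["edges"]])

  empty <- igraph::make_empty_graph(5, directed = FALSE)
  expect_error(fit_mple(empty, stat_config("edges")), "separated")
  expect_error(fit_mple(igraph::make_full_graph(5), stat_config("edges")),
               "separated")
})

test_that("MPLE on sampled edges-only graphs recovers the sampling theta", {
  theta <- qlogis(0.2)
  g <- sample_ergm(80, theta, stat_config("edges"), seed = 13)
  fit <- fit_mple(g, stat_config("edges"))
  expect_lt(abs(coef(fit)[["edges"]] - theta), 3 * fit$se[["edges"]])
})

test_that("tidy and glance summarize an MPLE fit", {
  g <- random_graph(40, 0.2, seed = 3)
  fit <- fit_mple(g, stat_config(c("edges", "two_stars"), decay = 0.5))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("edges", "two_stars"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_equal(gl$n, 40)
  expect_equal(gl$n_dyads, choose(40, 2))
})
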