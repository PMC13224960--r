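test_that("hand-enumerated topology of P3 and K4", {
  p3 <- glance(topology_report(toy_networks("p3")))
  expect_equal(p3$edge_density, 2 / 3)
  expect_equal(p3$average_path_length, 4 / 3)
  expect_equal(p3$diameter, 2)
  expect_equal(p3$global_efficiency, 5 / 6)

  k4 <- glance(topology_report(toy_networks("k4")))
  expect_equal(k4$edge_density, 1)
  expect_equal(k4$average_degree, 3)
  expect_equal(k4$average_clustering, 1)
  expect_equal(k4$transitivity, 1)
  expect_equal(k4$diameter, 1)

  net <- net_from_edgelist(tibble::tibble(from = c("a", "b", "c"),
                                          to = c("b", "c", "d"),
                                          r = c(0.7, -0.65, 0.8)))
  expect_equal(glance(topology_report(net))$prop_negative_edges, 1 / 3)
  expect_error(topology_report(as_metanet(igraph::make_empty_graph(0, FALSE))), "empty")
})

test_that("the metric registry is pinned at 17 names", {
  reg <- topology_metrics()
  expect_length(reg, 17L)
  expect_equal(attr(reg, "version"), "1")
  tr <- topology_report(toy_networks("k4"))
  expect_true(all(setdiff(reg, c("degree", "betweenness", "closeness", "eigenvector"))
                  %in% names(glance(tr))))
  expect_true(all(c("degree", "betweenness", "closeness", "eigenvector")
                  %in% names(tidy(tr))))
})

test_that("path metrics equal brute-force BFS recomputation on seeded graphs", {
  for (seed in 1:100) {
    n <- 5 + (seed %% 26)
    net <- random_metanet(n, 0.15, seed)
    if (igraph::ecount(net) == 0) next
    g <- glance(topology_report(net))
    o <- oracle_path_metrics(net)
    expect_equal(g$average_path_length, o$apl_lcc, tolerance = 1e-12)
    expect_equal(g$diameter, o$diameter_lcc)
    expect_equal(g$global_efficiency, o$efficiency, tolerance = 1e-12)
  }
})

test_that("natural connectivity matches its spectral definition and oracle", {
  k3 <- toy_networks("k3")
  expect_equal(natural_connectivity(k3), log((exp(2) + 2 * exp(-1)) / 3),
               tolerance = 1e-12)
  # edgeless graph
  iso <- as_metanet(igraph::make_empty_graph(3, directed = FALSE))
  expect_equal(natural_connectivity(iso), 0)
  # matrix-exponential-trace oracle + monotonicity under edge addition
  for (seed in 1:20) {
    net <- random_metanet(15, 0.2, seed)
    expect_equal(natural_connectivity(net), oracle_natural_connectivity(net),
                 tolerance = 1e-9)
    nc0 <- natural_connectivity(net)
    net2 <- igraph::add_edges(net, c("v1", "v2"))
    class(net2) <- class(net)
    if (!igraph::any_multiple(net2))
      expect_gte(natural_connectivity(net2), nc0 - 1e-12)
  }
})

test_that("power-law fit recovers a planted exponent and flags degeneracy", {
  # seeded draws from a discrete power law alpha = 2.5, xmin = 1
  degs <- withr::with_seed(31, {
    k <- 1:20000
    sample(k, 5000, replace = TRUE, prob = k^(-2.5))
  })
  fit <- fit_powerlaw_degree(degs)
  expect_gt(fit$alpha, 2.3)
  expect_lt(fit$alpha, 2.7)
  expect_false(fit$degenerate)

  # direct likelihood grid search at the fitted xmin as the oracle
  tail_ <- degs[degs >= fit$xmin]
  grid <- seq(1.6, 3.4, by = 0.001)
  ll <- vapply(grid, function(a)
    -length(tail_) * log(sum(((fit$xmin):1e5)^(-a))) - a * sum(log(tail_)),
    numeric(1))
  expect_equal(fit$alpha, grid[which.max(ll)], tolerance = 0.02)

  # relabelling-invariance: the fit depends only on the degree multiset
  net <- planted_module_network(rep(30, 3), 0.4, 0.05, seed = 2)$net
  f1 <- fit_powerlaw_degree(net)
  perm <- igraph::permute(net, sample(igraph::vcount(net)))
  class(perm) <- class(net)
  expect_equal(fit_powerlaw_degree(perm)$alpha, f1$alpha)

  expect_equal(fit_powerlaw_degree(rep(3L, 60))$degenerate, TRUE)
  expect_error(fit_powerlaw_degree(rep(1L, 10)), "at least 50")
})

test_that("null-model comparison preserves the model constraints", {
  net <- planted_module_network(rep(10, 3), 0.7, 0.05, seed = 3)$net
  z_er <- compare_random(net, "er_gnm", n_rand = 15, seed = 1)
  expect_true(all(c("observed", "null_mean", "null_sd", "z") %in% names(z_er)))
  # every ER replicate has the original n and m by construction; check via
  # direct regeneration with the same seed
  reps <- omicnet:::local_seed(1, replicate(15, {
    g <- igraph::sample_gnm(igraph::vcount(net), igraph::ecount(net), directed = FALSE)
    c(igraph::vcount(g), igraph::ecount(g))
  }))
  expect_true(all(reps[1, ] == igraph::vcount(net)))
  expect_true(all(reps[2, ] == igraph::ecount(net)))

  # degree-preserving rewires keep the degree sequence
  reps2 <- omicnet:::local_seed(2, replicate(10, {
    g <- igraph::rewire(net, igraph::keeping_degseq(niter = 10 * igraph::ecount(net)))
    identical(sort(igraph::degree(g)), sort(igraph::degree(net)))
  }))
  expect_true(all(reps2))

  # strongly clustered graph: positive clustering z-score vs ER
  cl_net <- toy_networks("two_k4_bridge")
  z <- compare_random(cl_net, "er_gnm", n_rand = 30, seed = 5)
  expect_gt(z$z[z$metric == "average_clustering"], 0)

  expect_error(compare_random(net, "er_gnm", n_rand = 3), "at least 10")
  expect_error(compare_random(toy_networks("k2"), "degree_preserving", 10), "2 edges")
})

test_that("robustness curves start intact, end empty and shrink monotonically", {
  star <- toy_networks("star10")
  rc <- robustness(star, "degree_targeted", fractions = c(0, 0.1, 0.5, 1), reps = 1)
  lcc <- rc$mean[rc$metric == "largest_component_fraction"]
  expect_equal(lcc[1], 1)                      # intact
  expect_equal(lcc[2], 1 / 10)                 # hub removed first
  expect_equal(lcc[length(lcc)], 0)            # all removed
  expect_true(all(diff(lcc) <= 1e-12))
  # fraction-0 row equals intact metrics
  expect_equal(rc$mean[rc$metric == "natural_connectivity"][1],
               natural_connectivity(star))
  expect_equal(rc$mean[rc$metric == "global_efficiency"][1],
               glance(topology_report(star))$global_efficiency)

  # random strategy: monotone LCC along every trajectory is guaranteed by
  # nested removal sets; check the averaged curve too
  net <- planted_module_network(rep(15, 2), 0.4, 0.1, seed = 6)$net
  rr <- robustness(net, "random", fractions = seq(0, 1, 0.25), reps = 10, seed = 9)
  lcc_r <- rr$mean[rr$metric == "largest_component_fraction"]
  expect_equal(lcc_r[1], 1)
  expect_equal(lcc_r[length(lcc_r)], 0)
  expect_true(all(diff(lcc_r) <= 1e-12))
  expect_identical(as.data.frame(robustness(net, "random", seq(0, 1, 0.5), 5, seed = 2)),
                   as.data.frame(robustness(net, "random", seq(0, 1, 0.5), 5, seed = 2)))
  expect_error(robustness(net, "random", reps = 0), "at least 1")
  expect_error(robustness(net, "random", fractions = c(0.5, 0.2)), "ascending")
})

test_that("weakening inter-module signal moves topology the expected way", {
  # Correlated-block data with a tunable shared factor: lambda controls the
  # inter-module correlation while blocks stay strongly coherent.
  make_net <- function(lambda, seed = 17) {
    tab <- planted_block_data(60, 40, 3, 0.6, 1, seed = seed)
    z <- omicnet:::local_seed(seed + 1000, rnorm(40))
    tab$values <- tab$values + lambda * matrix(z, 60, 40, byrow = TRUE)
    res <- c_net_calculate(tab, method = "pearson", adjust = "BH")
    c_net_build(res, r_threshold = 0.2, p_threshold = 0.05)
  }
  strong <- glance(topology_report(make_net(1.0)))
  weak <- glance(topology_report(make_net(0.2)))
  expect_gt(weak$modularity, strong$modularity)
  expect_gt(weak$average_path_length, strong$average_path_length)
  expect_lt(weak$global_efficiency, strong$global_efficiency)
  expect_lt(weak$natural_connectivity, strong$natural_connectivity)
})
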