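ring_square <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
# concave star-shaped pentagon ring
ring_star <- local({
  outer_t <- pi / 2 + 2 * pi * (0:4) / 5
  inner_t <- outer_t + pi / 5
  xs <- as.vector(rbind(cos(outer_t), 0.4 * cos(inner_t)))
  ys <- as.vector(rbind(sin(outer_t), 0.4 * sin(inner_t)))
  cbind(x = xs, y = ys)
})

test_that("deterministic layout conventions (circle, grid, star) hold", {
  k4 <- toy_networks("k4")
  coo <- c_net_layout(k4, "circle")
  expect_equal(coo$x, c(0, -1, 0, 1), tolerance = 1e-12)
  expect_equal(coo$y, c(1, 0, -1, 0), tolerance = 1e-12)

  g9 <- net_from_edgelist(tibble::tibble(from = paste0("n", 1:8), to = "n9", r = 1))
  coo9 <- c_net_layout(g9, "grid")
  expect_setequal(paste(coo9$x, coo9$y),
                  paste(rep(0:2, 3), rep(c(0, -1, -2), each = 3)))

  s <- c_net_layout(toy_networks("star10"), "star")
  expect_equal(s$x[1], 0)
  expect_equal(s$y[1], 0)
  expect_equal(sqrt(s$x[-1]^2 + s$y[-1]^2), rep(1, 9), tolerance = 1e-12)

  expect_error(c_net_layout(k4, "no_such_layout"), "registry")
})

test_that("seeded stochastic layouts are bit-reproducible", {
  net <- toy_networks("two_k4_bridge")
  a <- c_net_layout(net, "fr", seed = 7)
  b <- c_net_layout(net, "fr", seed = 7)
  expect_identical(a, b)
  c_ <- c_net_layout(net, "random", seed = 3)
  d <- c_net_layout(net, "random", seed = 3)
  expect_identical(c_, d)
})

test_that("as_polygon spaces groups strictly inside their side", {
  tt <- toy_networks("two_triangles")
  g3 <- setNames(c("g1", "g1", "g1", "g2", "g2", "g3"),
                 c("a", "b", "c", "d", "e", "f"))
  coo <- as_polygon(tt, g3, n_sides = 3)
  verts <- cbind(cos(pi / 2 + 2 * pi * (0:2) / 3), sin(pi / 2 + 2 * pi * (0:2) / 3))
  # single-node groups sit at side midpoints
  f_pos <- unlist(coo[coo$name == "f", c("x", "y")])
  expect_equal(unname(f_pos), (verts[3, ] + verts[1, ]) / 2, tolerance = 1e-12)
  # 3-node group at quarters of its side
  abc <- as.matrix(coo[match(c("a", "b", "c"), coo$name), c("x", "y")])
  for (k in 1:3)
    expect_equal(unname(abc[k, ]),
                 verts[1, ] + (k / 4) * (verts[2, ] - verts[1, ]), tolerance = 1e-12)
  # collinearity with side endpoints (cross product ~ 0) and strict interior
  for (k in 1:3) {
    v1 <- verts[2, ] - verts[1, ]; v2 <- abc[k, ] - verts[1, ]
    expect_lt(abs(v1[1] * v2[2] - v1[2] * v2[1]), 1e-9)
    expect_gt(min(sum((abc[k, ] - verts[1, ])^2), sum((abc[k, ] - verts[2, ])^2)), 1e-6)
  }
  expect_error(as_polygon(tt, g3, n_sides = 2), "groups")
})

test_that("as_polycircle centers group circles on polygon vertices", {
  tt <- toy_networks("two_triangles")
  g3 <- setNames(c("g1", "g1", "g1", "g2", "g2", "g3"),
                 c("a", "b", "c", "d", "e", "f"))
  coo <- as_polycircle(tt, g3, n_polygons = 3)
  anchors <- attr(coo, "anchors")
  expect_equal(nrow(anchors), 3L)
  expect_equal(unname(unlist(anchors[1, c("x", "y")])), c(0, 1), tolerance = 1e-12)
  # every node within 0.3 of its group center
  for (i in seq_len(nrow(coo))) {
    ctr <- anchors[anchors$group == coo$group[i], c("x", "y")]
    expect_lte(sqrt((coo$x[i] - ctr$x)^2 + (coo$y[i] - ctr$y)^2), 0.3 + 1e-9)
  }
  # single group on a 1-gon: center at the vertex-1 position (0, 1)
  k3 <- toy_networks("k3")
  coo1 <- as_polycircle(k3, setNames(rep("g", 3), c("a", "b", "c")), 1)
  expect_equal(unname(unlist(attr(coo1, "anchors")[1, c("x", "y")])), c(0, 1))
})

test_that("polygon-constrained layouts keep every node in bounds over many seeds", {
  net <- random_metanet(25, 0.2, 1)
  for (ring in list(ring_square, ring_star)) {
    for (seed in 1:60) {
      coo <- spatstat_layout(net, ring, "uniform_inside", seed = seed)
      expect_true(all(omicnet:::point_in_polygon(coo$x, coo$y, omicnet:::as_ring(ring))))
    }
    for (seed in 1:40) {
      coo <- spatstat_layout(net, ring, "random_inside", seed = seed)
      expect_true(all(omicnet:::point_in_polygon(coo$x, coo$y, omicnet:::as_ring(ring))))
    }
  }
})

test_that("uniform_inside sampling matches the area-uniform oracle", {
  big <- net_from_edgelist(tibble::tibble(from = paste0("a", 1:999),
                                          to = "hub", r = 1))
  coo <- spatstat_layout(big, ring_square, "uniform_inside", seed = 5)
  expect_equal(mean(coo$x), 0.5, tolerance = 0.05)
  expect_equal(mean(coo$y), 0.5, tolerance = 0.05)
  # naive rejection sampler as the independent uniformity oracle
  oracle <- withr::with_seed(5, {
    pts <- matrix(runif(4000), ncol = 2)
    pts[omicnet:::point_in_polygon(pts[, 1], pts[, 2], ring_square), , drop = FALSE]
  })
  expect_equal(mean(coo$x < 0.5), mean(oracle[, 1] < 0.5), tolerance = 0.06)
})

test_that("on_edges places nodes at arc-length positions on the boundary", {
  k4 <- toy_networks("k4")
  coo <- spatstat_layout(k4, ring_square, "on_edges")
  expect_equal(sort(paste(coo$x, coo$y)),
               sort(paste(c(0, 1, 1, 0), c(0, 0, 1, 1))))
  ring <- omicnet:::as_ring(ring_square)
  expect_true(all(omicnet:::point_in_polygon(coo$x, coo$y, ring)))
})

test_that("degenerate polygons are refused", {
  bowtie <- cbind(x = c(0, 1, 0, 1), y = c(0, 1, 1, 0))
  expect_error(spatstat_layout(toy_networks("k3"), bowtie, "uniform_inside"),
               "simple")
  flat <- cbind(x = c(0, 1, 2), y = c(0, 0, 0))
  expect_error(spatstat_layout(toy_networks("k3"), flat, "uniform_inside"),
               "zero-area")
})

test_that("g_layout centers groups on anchors, scales exactly and composes", {
  net <- toy_networks("two_triangles")
  groups <- setNames(c("L", "L", "L", "R", "R", "R"),
                     c("a", "b", "c", "d", "e", "f"))
  spec <- tibble::tibble(group = c("L", "R"), x = c(-2, 2), y = 0,
                         scale = 1, algorithm = c("grid", "circle"))
  coo <- g_layout(net, groups, spec)
  expect_equal(mean(coo$x[coo$group == "L"]), -2, tolerance = 1e-9)
  expect_equal(mean(coo$x[coo$group == "R"]), 2, tolerance = 1e-9)
  expect_equal(mean(coo$y), 0, tolerance = 1e-9)

  spec_half <- spec; spec_half$scale <- 0.5
  coo_half <- g_layout(net, groups, spec_half)
  d_full <- dist(as.matrix(coo[coo$group == "L", c("x", "y")]))
  d_half <- dist(as.matrix(coo_half[coo_half$group == "L", c("x", "y")]))
  expect_equal(as.vector(d_half), as.vector(d_full) / 2, tolerance = 1e-12)

  expect_error(g_layout(net, groups, spec[1, ]), "no spec row")
  expect_error(g_layout(net, groups[-1], spec), "group")
})

test_that("circle packing scales radii as sqrt(size) without overlaps", {
  net <- random_metanet(30, 0.1, 2)
  mod <- tibble::tibble(node = igraph::V(net)$name,
                        module = rep(c(1L, 1L, 1L, 2L, 3L), 6))
  coo <- g_layout_circlepack(net, mod)
  anchors <- attr(coo, "anchors")
  sizes <- table(mod$module)[anchors$group]
  expect_equal(anchors$scale, sqrt(as.numeric(sizes)), tolerance = 1e-12)
  for (i in seq_len(nrow(anchors) - 1)) {
    for (j in (i + 1):nrow(anchors)) {
      d <- sqrt((anchors$x[i] - anchors$x[j])^2 + (anchors$y[i] - anchors$y[j])^2)
      expect_gte(d, anchors$scale[i] + anchors$scale[j] - 1e-9)
    }
  }
  # 9:1 module sizes give a 3:1 radius ratio
  mod2 <- tibble::tibble(node = igraph::V(net)$name,
                         module = rep(c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L), 3))
  a2 <- attr(g_layout_circlepack(net, mod2), "anchors")
  expect_equal(max(a2$scale) / min(a2$scale),
               sqrt(27) / sqrt(3), tolerance = 1e-12)
  # single module: one circle at the origin
  a1 <- attr(g_layout_circlepack(net, tibble::tibble(node = igraph::V(net)$name,
                                                     module = 1L)), "anchors")
  expect_equal(c(a1$x, a1$y), c(0, 0))
})

test_that("multi-layer pseudo-3D mapping is the documented affine rule", {
  net <- toy_networks("two_triangles")
  layers <- setNames(c("A", "A", "A", "B", "B", "B"),
                     c("a", "b", "c", "d", "e", "f"))
  coo <- g_layout_multi_layer(net, layers, dz = 1, alpha = 60)
  # identical inner layouts (both triangles on the circle convention):
  # per-node vertical offset between layers is exactly dz
  ya <- coo$y[coo$group == "A"]; yb <- coo$y[coo$group == "B"]
  expect_equal(yb - ya, rep(1, 3), tolerance = 1e-12)
  # alpha = 90: no horizontal shear, x equals the inner layout x
  coo90 <- g_layout_multi_layer(net, layers, dz = 2, alpha = 90)
  inner <- c_net_layout(sample_subnetwork(net, c("a", "b", "c")), "circle")
  expect_equal(coo90$x[coo90$group == "A"], inner$x, tolerance = 1e-12)
  # invertibility given the layer index: recover inner coordinates
  a <- pi / 3
  y_inner <- (coo$y[coo$group == "B"] - 1) / sin(a)
  x_inner <- coo$x[coo$group == "B"] - y_inner * cos(a)
  expect_equal(x_inner, inner$x, tolerance = 1e-12)
  expect_equal(y_inner, inner$y, tolerance = 1e-12)
})

test_that("coordinate transforms are exact affine maps", {
  coo <- coors(c("a", "b"), c(1, 0), c(0, 2))
  rot <- transform_coors(coo, "rotate", angle = 90, origin = c(0, 0))
  expect_equal(rot$x, c(0, -2), tolerance = 1e-12)
  expect_equal(rot$y, c(1, 0), tolerance = 1e-12)
  mir <- transform_coors(coo, "mirror_x", origin = c(0, 0))
  expect_equal(mir$x, coo$x)
  expect_equal(mir$y, -coo$y)
  full <- transform_coors(coo, "rotate", angle = 360)
  expect_equal(full$x, coo$x, tolerance = 1e-12)
  expect_equal(full$y, coo$y, tolerance = 1e-12)
  sc <- transform_coors(coo, "scale", factor = 2)  # centroid-fixed
  expect_equal(mean(sc$x), mean(coo$x), tolerance = 1e-12)
  expect_equal(as.vector(dist(cbind(sc$x, sc$y))),
               2 * as.vector(dist(cbind(coo$x, coo$y))), tolerance = 1e-12)
  expect_error(transform_coors(coo, "scale", factor = 0), "non-zero")
})

test_that("every layout covers the node set with finite coordinates", {
  net <- random_metanet(12, 0.3, 4)
  groups <- setNames(rep(c("g1", "g2", "g3"), each = 4), igraph::V(net)$name)
  layouts <- list(
    c_net_layout(net, "circle"), c_net_layout(net, "grid"),
    c_net_layout(net, "fr", seed = 1),
    as_polygon(net, groups), as_polycircle(net, groups),
    spatstat_layout(net, ring_square, "uniform_inside", seed = 1),
    g_layout_multi_layer(net, groups))
  for (coo in layouts) {
    expect_setequal(coo$name, igraph::V(net)$name)
    expect_true(all(is.finite(coo$x)) && all(is.finite(coo$y)))
  }
})
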