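#' Planted correlated-block data
#'
#' Seeded generator of a feature x sample table with block-correlation
#' structure: the features of each block share a latent Gaussian factor
#' plus independent noise. With factor variance
#' `v = within_r * noise_sd^2 / (1 - within_r)` each within-block feature
#' pair has population correlation `within_r` while between-block pairs
#' are uncorrelated; memory stays O(features x samples) and the target
#' correlation is analytically controlled. `within_r = 0` gives pure
#' noise (the null used for p-value calibration). Generation is
#' bit-reproducible for a given seed.
#'
#' @param n_features number of features (divisible by `n_blocks`).
#' @param n_samples number of samples.
#' @param n_blocks number of correlated blocks.
#' @param within_r target within-block correlation in `[0, 1)`.
#' @param noise_sd independent noise standard deviation.
#' @param seed integer seed.
#' @return An [omics_table()] with block membership in `feature_meta`.
#' @export
planted_block_data <- function(n_features = 100, n_samples = 50, n_blocks = 5,
                               within_r = 0.7, noise_sd = 1, seed = 1) {
  if (within_r < 0 || within_r >= 1) abort("`within_r` must be in [0, 1)")
  if (n_features %% n_blocks != 0L)
    abort("`n_features` must be divisible by `n_blocks`")
  v <- within_r * noise_sd^2 / (1 - within_r)
  per <- n_features %/% n_blocks
  vals <- local_seed(seed, {
    m <- matrix(0, n_features, n_samples)
    for (b in seq_len(n_blocks)) {
      z <- rnorm(n_samples)
      rows <- ((b - 1L) * per + 1L):(b * per)
      m[rows, ] <- matrix(rep(sqrt(v) * z, per), nrow = per, byrow = TRUE) +
        matrix(rnorm(per * n_samples, sd = noise_sd), nrow = per)
    }
    m
  })
  fid <- sprintf("f%03d", seq_len(n_features))
  dimnames(vals) <- list(fid, sprintf("s%03d", seq_len(n_samples)))
  omics_table(vals, layer = "micro",
              feature_meta = tibble(feature = fid,
                                    block = rep(seq_len(n_blocks), each = per)))
}

#' Planted-module (stochastic block model) network
#'
#' Seeded SBM graph with known community structure for module-recovery
#' tests: within-module edge probability `p_in`, between-module `p_out`.
#' The planted partition is attached as the node attribute
#' `planted_module` and returned as a `module_assignment`-shaped tibble.
#'
#' @param module_sizes integer vector of module sizes.
#' @param p_in,p_out edge probabilities (recovery needs `p_in > p_out`).
#' @param seed integer seed.
#' @return A list with `net` (a [as_metanet()] network, edges `r = 1`) and
#'   `partition` (tibble `node`, `module`).
#' @export
planted_module_network <- function(module_sizes = rep(25, 4), p_in = 0.5,
                                   p_out = 0.02, seed = 1) {
  if (p_in <= p_out) warn("p_in <= p_out: planted modules are not recoverable")
  k <- length(module_sizes)
  pref <- matrix(p_out, k, k)
  diag(pref) <- p_in
  g <- local_seed(seed,
                  igraph::sample_sbm(sum(module_sizes), pref.matrix = pref,
                                     block.sizes = module_sizes))
  igraph::V(g)$name <- sprintf("n%03d", seq_len(sum(module_sizes)))
  igraph::V(g)$planted_module <- rep(seq_len(k), times = module_sizes)
  if (igraph::ecount(g)) {
    igraph::E(g)$r <- 1
    igraph::E(g)$p_adj <- 0
  }
  net <- as_metanet(g)
  list(net = net,
       partition = tibble(node = igraph::V(net)$name,
                          module = igraph::V(net)$planted_module))
}

#' Canonical toy networks
#'
#' Small hand-checkable graphs used across examples and tests: complete
#' graphs `k2`/`k3`/`k4`, the 3-path `p3`, two disjoint triangles
#' `two_triangles`, the 10-node star `star10` (hub `h` of degree 9) and
#' two 4-cliques joined by a single bridge `two_k4_bridge`. All edges
#' carry `r = 1`.
#'
#' @param name one of `"k2"`, `"k3"`, `"k4"`, `"p3"`, `"two_triangles"`,
#'   `"star10"`, `"two_k4_bridge"`.
#' @return A [as_metanet()] network.
#' @export
toy_networks <- function(name = c("k2", "k3", "k4", "p3", "two_triangles",
                                  "star10", "two_k4_bridge")) {
  name <- match.arg(name)
  edges <- switch(
    name,
    k2 = list(c("a", "b")),
    k3 = utils::combn(c("a", "b", "c"), 2, simplify = FALSE),
    k4 = utils::combn(c("a", "b", "c", "d"), 2, simplify = FALSE),
    p3 = list(c("a", "b"), c("b", "c")),
    two_triangles = c(utils::combn(c("a", "b", "c"), 2, simplify = FALSE),
                      utils::combn(c("d", "e", "f"), 2, simplify = FALSE)),
    star10 = lapply(sprintf("l%d", 1:9), function(l) c("h", l)),
    two_k4_bridge = c(utils::combn(c("a", "b", "c", "d"), 2, simplify = FALSE),
                      utils::combn(c("e", "f", "g", "h"), 2, simplify = FALSE),
                      list(c("d", "e")))
  )
  el <- do.call(rbind, edges)
  net_from_edgelist(tibble(from = el[, 1L], to = el[, 2L], r = 1, p_adj = 0))
}
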