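# Independent oracles used to cross-check the package's vectorized /
# library-backed computations.

# scalar per-pair correlation + analytic two-sided t p-value, written from
# the definitions (explicit sums, midranks via rank()); independent of the
# package's matrix path
oracle_pair <- function(x, y, method = "pearson") {
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  xm <- x - mean(x); ym <- y - mean(y)
  denom <- sqrt(sum(xm^2) * sum(ym^2))
  if (denom == 0) return(c(r = NA_real_, p = NA_real_))
  r <- sum(xm * ym) / denom
  n <- length(x)
  if (abs(r) >= 1) return(c(r = r, p = 0))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# modularity recomputed from the definition: Q = sum_c (w_c/W - (s_c/2W)^2)
# with w_c the intra-community weight, s_c the community strength
oracle_modularity <- function(net, membership, weights = NULL) {
  el <- igraph::as_edgelist(net, names = TRUE)
  memb <- stats::setNames(membership$module, membership$node)
  w <- weights %||% rep(1, nrow(el))
  W <- sum(w)
  comm <- sort(unique(memb))
  q <- 0
  for (cc in comm) {
    inside <- memb[el[, 1]] == cc & memb[el[, 2]] == cc
    w_c <- sum(w[inside])
    s_c <- sum(w[memb[el[, 1]] == cc]) + sum(w[memb[el[, 2]] == cc])
    q <- q + w_c / W - (s_c / (2 * W))^2
  }
  q
}

# all-pairs shortest-path matrix by breadth-first search from every node
oracle_dist_matrix <- function(net) {
  n <- igraph::vcount(net)
  adj <- igraph::as_adj_list(net)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(lapply(frontier, function(v) as.integer(adj[[v]]))))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# convenience wrappers over the distance oracle
oracle_path_metrics <- function(net) {
  d <- oracle_dist_matrix(net)
  off <- d[upper.tri(d)]
  finite <- off[is.finite(off)]
  list(
    apl_lcc = {
      comps <- igraph::components(net)
      lcc <- which(comps$membership == which.max(comps$csize))
      dl <- d[lcc, lcc][upper.tri(d[lcc, lcc])]
      if (length(dl)) mean(dl) else NA_real_
    },
    diameter_lcc = {
      comps <- igraph::components(net)
      lcc <- which(comps$membership == which.max(comps$csize))
      dl <- d[lcc, lcc][upper.tri(d[lcc, lcc])]
      if (length(dl)) max(dl) else 0
    },
    efficiency = if (length(off)) mean(ifelse(is.finite(off), 1 / off, 0)) else NA_real_
  )
}

oracle_natural_connectivity <- function(net) {
  a <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  a <- (a != 0) + 0
  log(sum(diag(expm_taylor(a))) / nrow(a))
}

# dense matrix exponential by scaling-and-squaring Taylor series (trace
# route of the natural-connectivity definition)
expm_taylor <- function(a, order = 30L) {
  nrm <- max(abs(a))
  s <- max(0L, ceiling(log2(max(nrm, 1))))
  a <- a / 2^s
  out <- diag(nrow(a))
  term <- diag(nrow(a))
  for (k in seq_len(order)) {
    term <- term %*% a / k
    out <- out + term
  }
  for (i in seq_len(s)) out <- out %*% out
  out
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# seeded Erdos-Renyi metanet for property loops
random_metanet <- function(n, p, seed) {
  g <- omicnet:::local_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- paste0("v", seq_len(n))
  if (igraph::ecount(g)) {
    igraph::E(g)$r <- omicnet:::local_seed(seed + 1e6,
                                           stats::runif(igraph::ecount(g), -1, 1))
    igraph::E(g)$p_adj <- 0.01
  }
  as_metanet(g)
}
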