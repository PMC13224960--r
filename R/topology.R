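#' The 17-metric topology registry
#'
#' Names and version of the metrics computed by [topology_report()]:
#' 13 global metrics and 4 per-node centralities. Path-based metrics use
#' unweighted topological distances; on a disconnected graph, average path
#' length and diameter are computed on the largest connected component
#' (and the report is flagged), while global efficiency stays global with
#' the `1/Inf = 0` convention.
#'
#' @return Character vector of metric names; the registry version is in
#'   `attr(, "version")`.
#' @export
topology_metrics <- function() {
  structure(c(
    # global
    "edge_density", "prop_negative_edges", "average_degree",
    "average_path_length", "diameter", "average_clustering", "transitivity",
    "global_efficiency", "modularity", "natural_connectivity",
    "n_components", "largest_component_fraction", "degree_centralization",
    # per-node
    "degree", "betweenness", "closeness", "eigenvector"
  ), version = "1")
}

#' Global and per-node topology report
#'
#' Computes the package's 17-metric registry (see [topology_metrics()]) on
#' the simple unweighted graph: counts, edge density, proportion of
#' negative edges (from the edge `sign` attribute; 0 if unsigned), average
#' degree, average path length and diameter (largest component), average
#' local clustering (degree < 2 contributes 0) and transitivity, global
#' efficiency, fast-greedy modularity, natural connectivity, component
#' structure and degree centralization, plus per-node degree, betweenness,
#' closeness and eigenvector centralities.
#'
#' @param net a [as_metanet()] network.
#' @return A `topology_report` with `glance()` (one-row global tibble) and
#'   `tidy()` (per-node tibble) methods.
#' @export
topology_report <- function(net) {
  stopifnot(inherits(net, "metanet"))
  n <- igraph::vcount(net)
  if (n == 0L) abort("empty graph")
  m <- igraph::ecount(net)
  comps <- igraph::components(net)
  lcc_ids <- which(comps$membership == which.max(comps$csize))
  lcc <- igraph::induced_subgraph(net, lcc_ids)
  sgn <- igraph::E(net)$sign
  deg <- igraph::degree(net)
  globals <- tibble(
    nodes = n,
    edges = m,
    edge_density = igraph::edge_density(net),
    prop_negative_edges = if (is.null(sgn) || m == 0L) 0 else mean(sgn < 0),
    average_degree = mean(deg),
    average_path_length = if (igraph::vcount(lcc) > 1L)
      igraph::mean_distance(lcc, directed = FALSE, weights = NA) else NA_real_,
    diameter = if (igraph::vcount(lcc) > 1L)
      igraph::diameter(lcc, directed = FALSE, unconnected = FALSE, weights = NA)
      else 0,
    average_clustering = mean(replace(igraph::transitivity(net, type = "local",
                                                           isolates = "zero"),
                                      deg < 2, 0)),
    transitivity = igraph::transitivity(net, type = "global"),
    global_efficiency = if (m == 0L) 0 else igraph::global_efficiency(net, weights = NA),
    modularity = if (m > 0L) modularity_q(detect_modules(net)) else NA_real_,
    natural_connectivity = natural_connectivity(net),
    n_components = comps$no,
    largest_component_fraction = max(comps$csize) / n,
    degree_centralization = if (n > 2L)
      igraph::centr_degree(net, loops = FALSE)$centralization else NA_real_
  )
  per_node <- tibble(
    node = igraph::V(net)$name,
    degree = as.integer(deg),
    betweenness = igraph::betweenness(net, weights = NA),
    closeness = suppressWarnings(igraph::closeness(net, weights = NA)),
    eigenvector = if (m > 0L) igraph::eigen_centrality(net, weights = NA)$vector
      else rep(0, n)
  )
  structure(list(globals = globals, per_node = per_node,
                 connected = comps$no == 1L,
                 registry_version = attr(topology_metrics(), "version")),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("<topology_report> registry v%s%s\n", x$registry_version,
              if (!x$connected) " (disconnected: path metrics on largest component)" else ""))
  print(glance.topology_report(x))
  invisible(x)
}

#' @rdname topology_report
#' @param x a `topology_report`.
#' @param ... unused.
#' @export
glance.topology_report <- function(x, ...) x$globals

#' @rdname topology_report
#' @export
tidy.topology_report <- function(x, ...) x$per_node

#' Natural connectivity
#'
#' `ln((1/N) * sum_i exp(lambda_i))` over the adjacency eigenvalues of the
#' simple unweighted graph — the log average Estrada weight of closed
#' walks, a spectral measure of redundancy of alternative paths that
#' never decreases when an edge is added. Computed with a max-shift for
#' numerical stability.
#'
#' @param net a [as_metanet()] network (or igraph).
#' @return Numeric scalar; 0 for an edgeless graph.
#' @export
natural_connectivity <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) abort("empty graph")
  a <- igraph::as_adjacency_matrix(net, sparse = FALSE, type = "both")
  a <- (a != 0) + 0
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(ev)
  mx + log(mean(exp(ev - mx)))
}

#' Discrete power-law fit of the degree distribution
#'
#' Clauset-style discrete maximum-likelihood estimate of the power-law
#' exponent with `xmin` chosen by minimal Kolmogorov-Smirnov distance
#' (via [igraph::fit_power_law()]). This is a descriptive report of the
#' fitted exponent, never a verdict on scale-freeness.
#'
#' @param net a [as_metanet()] network, or a numeric vector of degrees.
#' @return A tibble with `alpha`, `xmin`, `ks_distance`, `n_tail` (degrees
#'   >= xmin) and `degenerate` (TRUE when all degrees are equal).
#' @export
fit_powerlaw_degree <- function(net) {
  d <- if (inherits(net, "metanet")) igraph::degree(net) else as.numeric(net)
  d <- d[d >= 1]
  if (length(d) < 50L)
    abort(sprintf("need at least 50 nodes with degree >= 1, got %d", length(d)))
  if (length(unique(d)) == 1L)
    return(tibble(alpha = NA_real_, xmin = unique(d), ks_distance = NA_real_,
                  n_tail = length(d), degenerate = TRUE))
  fit <- igraph::fit_power_law(d, implementation = "plfit")
  tibble(alpha = fit$alpha, xmin = fit$xmin, ks_distance = fit$KS.stat,
         n_tail = sum(d >= fit$xmin), degenerate = FALSE)
}

#' Compare observed topology with randomized networks
#'
#' Generates `n_rand` null networks — Erdos-Renyi G(n, m) with the same
#' node and edge counts (`er_gnm`) or degree-preserving rewiring by
#' `10 * m` double-edge swaps rejecting multi-edges and self-loops
#' (`degree_preserving`) — and reports per-metric z-scores
#' `(observed - null mean) / null sd` (`NA` when the null sd is 0).
#'
#' @param net a [as_metanet()] network.
#' @param model `"er_gnm"` or `"degree_preserving"`.
#' @param n_rand number of null replicates (>= 10).
#' @param seed integer seed.
#' @return A tibble with `metric`, `observed`, `null_mean`, `null_sd`, `z`.
#' @export
compare_random <- function(net, model = c("er_gnm", "degree_preserving"),
                           n_rand = 100, seed = 1) {
  stopifnot(inherits(net, "metanet"))
  model <- match.arg(model)
  if (n_rand < 10) abort("`n_rand` must be at least 10")
  m <- igraph::ecount(net)
  if (model == "degree_preserving" && m < 2L)
    abort("degree_preserving rewiring needs at least 2 edges")
  metric_vec <- function(g) {
    if ("weight" %in% igraph::edge_attr_names(g))
      g <- igraph::delete_edge_attr(g, "weight")
    comps <- igraph::components(g)
    lcc <- igraph::induced_subgraph(g, which(comps$membership == which.max(comps$csize)))
    c(average_path_length = if (igraph::vcount(lcc) > 1L)
        igraph::mean_distance(lcc, directed = FALSE, weights = NA) else NA_real_,
      diameter = if (igraph::vcount(lcc) > 1L)
        igraph::diameter(lcc, directed = FALSE, weights = NA) else 0,
      average_clustering = mean(igraph::transitivity(g, type = "local",
                                                     isolates = "zero")),
      transitivity = igraph::transitivity(g, type = "global"),
      global_efficiency = igraph::global_efficiency(g, weights = NA),
      modularity = igraph::modularity(igraph::cluster_fast_greedy(g, weights = NULL)),
      natural_connectivity = natural_connectivity(g))
  }
  obs <- metric_vec(net)
  nulls <- local_seed(seed, {
    purrr::map(seq_len(n_rand), function(i) {
      g <- if (model == "er_gnm")
        igraph::sample_gnm(igraph::vcount(net), m, directed = FALSE)
      else igraph::rewire(net, igraph::keeping_degseq(niter = 10 * m))
      metric_vec(g)
    })
  })
  null_mat <- do.call(rbind, nulls)
  mu <- colMeans(null_mat, na.rm = TRUE)
  sdev <- apply(null_mat, 2L, sd, na.rm = TRUE)
  tibble(metric = names(obs), observed = unname(obs),
         null_mean = unname(mu), null_sd = unname(sdev),
         z = unname(ifelse(sdev > 0, (obs - mu) / sdev, NA_real_)))
}

#' Robustness under node removal
#'
#' Removes growing node fractions and tracks largest-component fraction
#' (relative to the intact node count), natural connectivity and global
#' efficiency. Removals are cumulative along each trajectory (nested
#' sets). Targeted strategies rank nodes once on the intact network
#' (static order, ties broken by node id); the random strategy averages
#' `reps` seeded trajectories.
#'
#' @param net a [as_metanet()] network.
#' @param strategy `"random"`, `"degree_targeted"` or
#'   `"betweenness_targeted"`.
#' @param fractions ascending removal fractions in `[0, 1]` (0 = intact).
#' @param reps number of random trajectories (ignored for targeted).
#' @param seed integer seed for random removals.
#' @return A `robustness_curve` tibble: `fraction`, `metric`, `mean`,
#'   `sd`; attributes record strategy, reps and seed.
#' @export
robustness <- function(net, strategy = c("random", "degree_targeted",
                                         "betweenness_targeted"),
                       fractions = seq(0, 1, by = 0.1), reps = 20, seed = 1) {
  stopifnot(inherits(net, "metanet"))
  strategy <- match.arg(strategy)
  if (reps < 1) abort("`reps` must be at least 1")
  if (is.unsorted(fractions, strictly = TRUE) || any(fractions < 0 | fractions > 1))
    abort("`fractions` must be strictly ascending within [0, 1]")
  n <- igraph::vcount(net)
  nodes <- igraph::V(net)$name
  snapshot <- function(g) {
    if (igraph::vcount(g) == 0L)
      return(c(largest_component_fraction = 0, natural_connectivity = NA_real_,
               global_efficiency = NA_real_))
    comps <- igraph::components(g)
    c(largest_component_fraction = max(comps$csize) / n,
      natural_connectivity = natural_connectivity(g),
      global_efficiency = if (igraph::ecount(g) == 0L) 0
        else igraph::global_efficiency(g, weights = NA))
  }
  trajectory <- function(order) {
    vapply(fractions, function(f) {
      k <- round(f * n)
      g <- igraph::delete_vertices(net, order[seq_len(k)])
      snapshot(g)
    }, numeric(3))
  }
  if (strategy == "random") {
    trajs <- local_seed(seed, purrr::map(seq_len(reps),
                                         function(i) trajectory(sample(nodes))))
  } else {
    score <- if (strategy == "degree_targeted") igraph::degree(net)
      else igraph::betweenness(net, weights = NA)
    trajs <- list(trajectory(nodes[order(-score, nodes)]))
  }
  arr <- simplify2array(trajs)           # metric x fraction x rep
  mean_mat <- apply(arr, c(1, 2), mean)
  sd_mat <- if (length(trajs) > 1L) apply(arr, c(1, 2), sd) else mean_mat * 0
  out <- tibble(
    fraction = rep(fractions, each = 3L),
    metric = rep(rownames(mean_mat), times = length(fractions)),
    mean = as.vector(mean_mat),
    sd = as.vector(sd_mat))
  structure(out, class = c("robustness_curve", class(out)),
            strategy = strategy, reps = length(trajs), seed = seed)
}

#' Plot a robustness curve
#'
#' @param object a `robustness_curve` from [robustness()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.robustness_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fraction, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = sprintf("fraction removed (%s)", attr(object, "strategy")),
                  y = NULL)
}
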