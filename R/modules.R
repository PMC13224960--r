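#' Detect modules by fast greedy modularity optimization
#'
#' Runs the Clauset-Newman-Moore greedy agglomeration (via
#' [igraph::cluster_fast_greedy()]) maximizing weighted modularity, with
#' edge weights `|r|` (1 where absent); negative correlations contribute
#' their magnitude, the sign stays an edge attribute. Module ids are
#' relabelled 1-based by descending module size (ties broken by smallest
#' member name) so the labelling is deterministic.
#'
#' @param net a [as_metanet()] network.
#' @return A `module_assignment`: tibble with columns `node`, `module`, and
#'   attributes `Q` (modularity of the partition) and `sizes`.
#' @export
detect_modules <- function(net) {
  stopifnot(inherits(net, "metanet"))
  if (igraph::vcount(net) == 0L) abort("cannot detect modules in an empty graph")
  w <- igraph::E(net)$r
  w <- if (is.null(w)) rep(1, igraph::ecount(net)) else abs(w)
  w[is.na(w)] <- 1
  g <- net
  cl <- igraph::cluster_fast_greedy(g, weights = if (length(w)) w else NULL)
  # cut the dendrogram at the max-modularity step ourselves: membership()
  # can return a suboptimal cut when merges tie (e.g. a single edge)
  memb <- igraph::cut_at(cl, steps = which.max(cl$modularity) - 1L)
  q <- igraph::modularity(g, memb, weights = if (length(w)) w else NULL)
  nodes <- igraph::V(net)$name
  first_member <- vapply(split(nodes, memb), min, character(1))
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), first_member)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  out <- tibble(node = nodes, module = relabel[as.integer(memb)])
  structure(out, class = c("module_assignment", class(out)),
            Q = q, sizes = as.integer(sort(table(out$module), decreasing = TRUE)))
}

#' Modularity of a module assignment
#' @param modules a `module_assignment` from [detect_modules()].
#' @return Modularity Q (numeric scalar).
#' @export
modularity_q <- function(modules) {
  stopifnot(inherits(modules, "module_assignment"))
  attr(modules, "Q")
}

#' Zi-Pi topological role classification
#'
#' Classifies nodes by their within-module degree z-score (Zi) and
#' participation coefficient (Pi). For node `i` in module `s`,
#' `Zi = (k_is - mean_s) / sd_s` where `k_is` counts the node's links into
#' its own module and the mean/sd are taken over the members of `s`
#' (`sd_s = 0` gives `Zi = 0`); `Pi = 1 - sum_m (k_im / k_i)^2` over
#' modules `m`. Degrees are unweighted. Roles use the Guimera-Amaral
#' cutoffs `Zi >= 2.5`, `Pi >= 0.62`: module hub (high Zi only), connector
#' (high Pi only), network hub (both), peripheral (neither). Isolated
#' nodes have undefined Pi (`NA`) and are reported peripheral.
#'
#' @param net a [as_metanet()] network.
#' @param modules a `module_assignment` covering the nodes of `net`, e.g.
#'   from [detect_modules()].
#' @param zi_threshold,pi_threshold role cutoffs.
#' @return A `node_roles` tibble: `node`, `module`, `degree`,
#'   `within_degree`, `zi`, `pi`, `role`.
#' @export
zipi <- function(net, modules, zi_threshold = 2.5, pi_threshold = 0.62) {
  stopifnot(inherits(net, "metanet"))
  nodes <- igraph::V(net)$name
  memb <- modules$module[match(nodes, modules$node)]
  if (anyNA(memb)) abort("`modules` must cover every node of `net`")
  el <- igraph::as_edgelist(net, names = FALSE)
  n <- length(nodes)
  k <- unname(igraph::degree(net))
  n_mod <- max(memb)
  # k_im: links of node i into module m
  kim <- matrix(0L, n, n_mod)
  if (nrow(el)) {
    for (e in seq_len(nrow(el))) {
      u <- el[e, 1L]; v <- el[e, 2L]
      kim[u, memb[v]] <- kim[u, memb[v]] + 1L
      kim[v, memb[u]] <- kim[v, memb[u]] + 1L
    }
  }
  kis <- kim[cbind(seq_len(n), memb)]
  mean_s <- tapply(kis, memb, mean)[as.character(memb)]
  sd_s <- tapply(kis, memb, sd)[as.character(memb)]
  sd_s[is.na(sd_s)] <- 0
  zi <- as.numeric(ifelse(sd_s > 0, (kis - mean_s) / sd_s, 0))
  pi <- ifelse(k > 0, 1 - rowSums((kim / pmax(k, 1L))^2), NA_real_)
  role <- dplyr::case_when(
    k == 0L ~ "peripheral",
    zi >= zi_threshold & pi >= pi_threshold ~ "network_hub",
    zi >= zi_threshold ~ "module_hub",
    pi >= pi_threshold ~ "connector",
    TRUE ~ "peripheral"
  )
  out <- tibble(node = nodes, module = memb, degree = as.integer(k),
                within_degree = as.integer(kis), zi = unname(zi), pi = pi,
                role = role)
  structure(out, class = c("node_roles", class(out)),
            thresholds = c(zi = zi_threshold, pi = pi_threshold))
}

#' Plot node roles in the Zi-Pi plane
#'
#' @param object a `node_roles` tibble from [zipi()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.node_roles <- function(object, ...) {
  th <- attr(object, "thresholds")
  ggplot2::ggplot(object, ggplot2::aes(.data$pi, .data$zi, colour = .data$role)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = th[["zi"]], linetype = 2) +
    ggplot2::geom_vline(xintercept = th[["pi"]], linetype = 2) +
    ggplot2::labs(x = "participation coefficient (Pi)",
                  y = "within-module degree z-score (Zi)")
}
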