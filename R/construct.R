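#' Build a thresholded network from a correlation result
#'
#' Keeps an edge for every pair with `|r| > r_threshold` **and**
#' `p_adj < p_threshold` (both strict). Isolated nodes are dropped unless
#' `keep_isolated = TRUE`. The thresholds and correlation method are
#' recorded as graph attributes for provenance.
#'
#' @param corr a `cor_res` from [c_net_calculate()].
#' @param r_threshold absolute-correlation cutoff in `(0, 1)`; e.g. the
#'   value chosen by [rmt_scan()].
#' @param p_threshold adjusted-p cutoff in `(0, 1)`, or `NULL` to filter on
#'   `|r|` only.
#' @param keep_isolated keep nodes with no passing edge?
#' @return A [as_metanet()] network (possibly empty, with a warning).
#' @export
c_net_build <- function(corr, r_threshold = 0.6, p_threshold = 0.05,
                        keep_isolated = FALSE) {
  stopifnot(inherits(corr, "cor_res"))
  stop_if_not_scalar_number(r_threshold, "r_threshold")
  if (r_threshold <= 0 || r_threshold >= 1) abort("`r_threshold` must be in (0, 1)")
  if (!is.null(p_threshold)) {
    stop_if_not_scalar_number(p_threshold, "p_threshold")
    if (p_threshold <= 0 || p_threshold >= 1) abort("`p_threshold` must be in (0, 1)")
    if (corr$adjust == "none")
      abort("correlation result has no p-value adjustment; rerun c_net_calculate with adjust != \"none\" or set p_threshold = NULL")
  }
  pairs <- tidy.cor_res(corr)
  pass <- !is.na(pairs$r) & abs(pairs$r) > r_threshold
  if (!is.null(p_threshold)) pass <- pass & !is.na(pairs$p_adj) & pairs$p_adj < p_threshold
  kept <- pairs[pass, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warn("no pair passed the thresholds; returning empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_graph_attr(g, "method", corr$method)
    g <- igraph::set_graph_attr(g, "r_threshold", r_threshold)
    g <- igraph::set_graph_attr(g, "p_threshold", p_threshold %||% NA_real_)
    class(g) <- unique(c("metanet", class(g)))
    return(g)
  }
  nodes <- if (keep_isolated) union(corr$row_ids, corr$col_ids) else
    union(kept$row, kept$col)
  node_attrs <- tibble(name = nodes)
  if (corr$mode == "inter") {
    node_attrs$layer <- ifelse(nodes %in% corr$row_ids, corr$row_layer, corr$col_layer)
  } else {
    node_attrs$layer <- corr$row_layer
  }
  net <- net_from_edgelist(
    tibble(from = kept$row, to = kept$col, r = kept$r, p_adj = kept$p_adj),
    node_attrs = node_attrs
  )
  net <- igraph::set_graph_attr(net, "method", corr$method)
  net <- igraph::set_graph_attr(net, "r_threshold", r_threshold)
  net <- igraph::set_graph_attr(net, "p_threshold", p_threshold %||% NA_real_)
  net <- igraph::set_graph_attr(net, "n_samples", corr$n)
  class(net) <- unique(c("metanet", class(net)))
  net
}

#' Assemble a multi-omics network from inter-omics correlation blocks
#'
#' Each block is an inter-omics `cor_res` (e.g. microbial exposome vs
#' transcriptome, chemical exposome vs transcriptome); per-block `|r|` and
#' adjusted-p thresholds are applied independently and the passing edges
#' united into one network whose nodes carry their omics `layer`. A feature
#' id appearing under two different layers is an error. Per-block tallies
#' of positive and negative edges are attached for reporting.
#'
#' @param corr_blocks list of inter-omics `cor_res` objects with distinct
#'   layer tags.
#' @param thresholds data frame with one row per block: columns
#'   `r_threshold` and `p_threshold` (recycled if a single row).
#' @param keep_isolated keep nodes with no passing edge?
#' @return A [as_metanet()] network; `attr(, "sign_tally")` is a tibble
#'   with per-block edge counts by sign.
#' @export
assemble_multiomics <- function(corr_blocks, thresholds, keep_isolated = FALSE) {
  stopifnot(is.list(corr_blocks), length(corr_blocks) >= 1L)
  thresholds <- as_tibble(thresholds)
  if (nrow(thresholds) == 1L)
    thresholds <- thresholds[rep(1L, length(corr_blocks)), ]
  if (nrow(thresholds) != length(corr_blocks))
    abort("`thresholds` must have one row per block (or a single row)")

  edges <- list(); layer_of <- character(); tally <- list()
  for (i in seq_along(corr_blocks)) {
    blk <- corr_blocks[[i]]
    stopifnot(inherits(blk, "cor_res"))
    if (blk$mode != "inter") abort("every block must be an inter-omics cor_res")
    pairs <- tidy.cor_res(blk)
    pass <- !is.na(pairs$r) & abs(pairs$r) > thresholds$r_threshold[i] &
      !is.na(pairs$p_adj) & pairs$p_adj < thresholds$p_threshold[i]
    kept <- pairs[pass, , drop = FALSE]
    edges[[i]] <- tibble(from = kept$row, to = kept$col, r = kept$r, p_adj = kept$p_adj)
    tally[[i]] <- tibble(
      block = i,
      layers = paste(blk$row_layer, blk$col_layer, sep = "-"),
      n_positive = sum(kept$r > 0), n_negative = sum(kept$r < 0))
    ids <- c(blk$row_ids, blk$col_ids)
    lys <- c(rep(blk$row_layer, length(blk$row_ids)),
             rep(blk$col_layer, length(blk$col_ids)))
    new <- !duplicated(ids)
    conflict <- ids %in% names(layer_of) & lys != layer_of[ids]
    conflict[is.na(conflict)] <- FALSE
    if (any(conflict))
      abort(sprintf("id(s) present in more than one layer: %s",
                    paste(unique(ids[conflict]), collapse = ", ")))
    add <- ids[new & !(ids %in% names(layer_of))]
    layer_of[add] <- lys[new & !(ids %in% names(layer_of))]
  }
  all_edges <- dplyr::bind_rows(edges)
  if (nrow(all_edges) == 0L && !keep_isolated) {
    warn("no edge passed in any block; returning empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    class(g) <- unique(c("metanet", class(g)))
    attr(g, "sign_tally") <- dplyr::bind_rows(tally)
    return(g)
  }
  nodes <- if (keep_isolated) names(layer_of) else union(all_edges$from, all_edges$to)
  net <- net_from_edgelist(all_edges,
                           node_attrs = tibble(name = nodes,
                                               layer = unname(layer_of[nodes])))
  net <- igraph::set_graph_attr(net, "n_blocks", length(corr_blocks))
  class(net) <- unique(c("metanet", class(net)))
  attr(net, "sign_tally") <- dplyr::bind_rows(tally)
  net
}
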