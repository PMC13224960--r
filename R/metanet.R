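#' Attributed correlation network
#'
#' A `metanet` is an undirected, simple [igraph::igraph] graph carrying the
#' attribute conventions used throughout the package: node attribute `name`
#' (opaque string id) plus optional `layer`, `module`, `role`, `zi`, `pi`,
#' `size`; edge attributes `r` (correlation), `sign` (+1 when `r > 0`, -1
#' otherwise), `weight` (`|r|`) and `p_adj`. All package operations
#' preserve the class and its invariants: no self-loops, no duplicate
#' edges, `sign`/`weight` consistent with `r`.
#'
#' @param graph an igraph object.
#' @return A `metanet` object.
#' @export
as_metanet <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) graph <- igraph::as_undirected(graph, mode = "collapse")
  if (is.null(igraph::V(graph)$name))
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  if (!is.null(igraph::E(graph)$r)) {
    igraph::E(graph)$sign <- ifelse(igraph::E(graph)$r > 0, 1L, -1L)
    igraph::E(graph)$weight <- abs(igraph::E(graph)$r)
  }
  class(graph) <- unique(c("metanet", class(graph)))
  validate_metanet(graph)
  graph
}

validate_metanet <- function(net) {
  if (any(igraph::which_loop(net))) abort("metanet must not contain self-loops")
  if (any(igraph::which_multiple(net))) abort("metanet must not contain duplicate edges")
  r <- igraph::E(net)$r
  if (!is.null(r)) {
    sgn <- igraph::E(net)$sign
    w <- igraph::E(net)$weight
    ok <- is.na(r) | (sgn == ifelse(r > 0, 1L, -1L) & abs(w - abs(r)) <= 1e-12)
    if (!all(ok)) abort("edge sign/weight inconsistent with r")
  }
  invisible(net)
}

#' @export
print.metanet <- function(x, ...) {
  cat(sprintf("<metanet> %d nodes, %d edges\n", igraph::vcount(x), igraph::ecount(x)))
  ga <- igraph::graph_attr(x)
  if (length(ga))
    cat("  graph attrs:", paste(names(ga), collapse = ", "), "\n")
  invisible(x)
}

#' Node and edge tables of a network
#'
#' Tabular (tibble) views of a [as_metanet()] network's attributes, the
#' data-frame-first surface used by the rest of the package.
#'
#' @param net a `metanet`.
#' @return `net_nodes()`: one row per node with a `name` column plus every
#'   node attribute. `net_edges()`: one row per edge with `from`/`to`
#'   endpoint columns plus every edge attribute.
#' @export
net_nodes <- function(net) {
  stopifnot(inherits(net, "metanet"))
  attrs <- igraph::vertex_attr(net)
  as_tibble(attrs[order(names(attrs) != "name")])
}

#' @rdname net_nodes
#' @export
net_edges <- function(net) {
  stopifnot(inherits(net, "metanet"))
  el <- igraph::as_edgelist(net, names = TRUE)
  out <- tibble(from = el[, 1L], to = el[, 2L])
  for (a in names(igraph::edge_attr(net))) out[[a]] <- igraph::edge_attr(net, a)
  out
}

#' Build a network from an edge list
#'
#' Rows are `(from, to, r, p_adj)` records. The edge identity is the
#' unordered pair: duplicate `(u,v)`/`(v,u)` rows are collapsed keeping the
#' smallest `p_adj` (ties broken by largest `|r|`). `sign` and `weight` are
#' derived from `r`.
#'
#' @param edges data frame with columns `from`, `to`, `r` and optionally
#'   `p_adj`.
#' @param node_attrs optional data frame of node attributes keyed by a
#'   `name` column; may introduce isolated nodes.
#' @return A [as_metanet()] network.
#' @export
#' @examples
#' net_from_edgelist(data.frame(from = "a", to = "b", r = 0.7, p_adj = 0.01))
net_from_edgelist <- function(edges, node_attrs = NULL) {
  edges <- as_tibble(edges)
  need <- c("from", "to", "r")
  if (!all(need %in% names(edges)))
    abort("`edges` must have columns from, to, r")
  if (!is.numeric(edges$r)) abort("column `r` must be numeric")
  if (!"p_adj" %in% names(edges)) edges$p_adj <- NA_real_
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to))
    abort(sprintf("self-loop row(s): %s",
                  paste(unique(edges$from[edges$from == edges$to]), collapse = ", ")))
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges <- edges |>
    dplyr::mutate(.a = a, .b = b) |>
    dplyr::arrange(.data$.a, .data$.b, .data$p_adj, dplyr::desc(abs(.data$r))) |>
    dplyr::distinct(.data$.a, .data$.b, .keep_all = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$.a, to = edges$.b, r = edges$r, p_adj = edges$p_adj),
    directed = FALSE,
    vertices = if (!is.null(node_attrs)) as.data.frame(node_attrs) else NULL
  )
  as_metanet(g)
}

#' Annotate network nodes from a metadata table
#'
#' Columns of `table` (other than the key) become node attributes for the
#' nodes whose id matches the key column. Unmatched nodes keep their
#' existing attribute values (or `NA`); unmatched table rows are counted in
#' the attached report.
#'
#' @param net a `metanet`.
#' @param table data frame of node metadata.
#' @param key name of the id column in `table`.
#' @return The annotated network. The report is available as
#'   `attr(, "annotation_report")`: a list with `n_matched`,
#'   `unmatched_nodes` and `unmatched_rows`.
#' @export
annotate_nodes <- function(net, table, key = "name") {
  stopifnot(inherits(net, "metanet"))
  table <- as_tibble(table)
  if (nrow(table) == 0L || ncol(table) == 0L) {
    attr(net, "annotation_report") <- list(
      n_matched = 0L, unmatched_nodes = igraph::V(net)$name,
      unmatched_rows = character())
    return(net)
  }
  if (!key %in% names(table))
    abort(sprintf("key column '%s' absent from annotation table", key))
  ids <- as.character(table[[key]])
  nodes <- igraph::V(net)$name
  idx <- match(nodes, ids)
  for (col in setdiff(names(table), key)) {
    vals <- table[[col]][idx]
    old <- igraph::vertex_attr(net, col)
    if (!is.null(old)) vals[is.na(idx)] <- old[is.na(idx)]
    net <- igraph::set_vertex_attr(net, col, value = vals)
  }
  class(net) <- unique(c("metanet", class(net)))
  attr(net, "annotation_report") <- list(
    n_matched = sum(!is.na(idx)),
    unmatched_nodes = nodes[is.na(idx)],
    unmatched_rows = setdiff(ids, nodes))
  net
}

#' Set-based comparison of two networks
#'
#' Compares node and edge sets (edge identity ignores orientation).
#'
#' @param netA,netB `metanet` objects with comparable node ids.
#' @return A tibble with one row per element type (`node`, `edge`) and
#'   columns `intersection`, `union`, `only_a`, `only_b`.
#' @export
compare_nets <- function(netA, netB) {
  stopifnot(inherits(netA, "metanet"), inherits(netB, "metanet"))
  edge_keys <- function(g) {
    el <- igraph::as_edgelist(g, names = TRUE)
    if (nrow(el) == 0L) return(character())
    paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "\r")
  }
  na <- igraph::V(netA)$name; nb <- igraph::V(netB)$name
  ea <- edge_keys(netA); eb <- edge_keys(netB)
  tibble(
    element = c("node", "edge"),
    intersection = c(length(intersect(na, nb)), length(intersect(ea, eb))),
    union = c(length(union(na, nb)), length(union(ea, eb))),
    only_a = c(length(setdiff(na, nb)), length(setdiff(ea, eb))),
    only_b = c(length(setdiff(nb, na)), length(setdiff(eb, ea)))
  )
}

#' Extract the subnetwork induced by a set of present nodes
#'
#' Used to build sample-specific subnetworks: the induced subgraph on the
#' features present in one sample, inheriting all attributes.
#'
#' @param net a `metanet`.
#' @param present character vector of node ids present; ids not in the
#'   network are ignored with a warning.
#' @return The induced `metanet` subgraph.
#' @export
sample_subnetwork <- function(net, present) {
  stopifnot(inherits(net, "metanet"))
  present <- as.character(present)
  extra <- setdiff(present, igraph::V(net)$name)
  if (length(extra))
    warn(sprintf("%d present id(s) not in network (ignored): %s",
                 length(extra), paste(head(extra, 5L), collapse = ", ")))
  keep <- intersect(igraph::V(net)$name, present)
  if (length(keep) == 0L)
    warn("no present nodes found in network; returning empty network")
  sub <- igraph::induced_subgraph(net, keep)
  class(sub) <- unique(c("metanet", class(sub)))
  sub
}
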