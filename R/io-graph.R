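# Graph file I/O: GraphML (attribute-lossless, canonical output), Pajek
# (documented lossy subset: id, label, coordinates, weight) and edge-list
# TSV (source, target, r, sign, p_adj). All writers emit UTF-8 with LF
# line endings; GraphML output is canonical (nodes sorted by id, edges by
# endpoint pair, attributes lexicographic) so write -> read -> write is
# byte-identical.

#' Read or write a network file
#'
#' Dispatches on `format`: `"graphml"` round-trips every string/numeric
#' node and edge attribute; `"pajek"` preserves only node ids/labels,
#' coordinates (`x`, `y`) and edge weights; `"edgelist_tsv"` writes the
#' columns `source`, `target`, `r`, `sign`, `p_adj`.
#'
#' @param path file path.
#' @param format one of `"graphml"`, `"pajek"`, `"edgelist_tsv"`.
#' @param net a [as_metanet()] network (writer only).
#' @return `read_graph_file()` returns a `metanet`; `write_graph_file()`
#'   returns `path` invisibly.
#' @export
read_graph_file <- function(path, format = c("graphml", "pajek", "edgelist_tsv")) {
  format <- match.arg(format)
  switch(format,
         graphml = read_graphml(path),
         pajek = read_pajek(path),
         edgelist_tsv = read_edgelist_tsv(path))
}

#' @rdname read_graph_file
#' @export
write_graph_file <- function(net, path, format = c("graphml", "pajek", "edgelist_tsv")) {
  stopifnot(inherits(net, "metanet"))
  format <- match.arg(format)
  switch(format,
         graphml = write_graphml(net, path),
         pajek = write_pajek(net, path),
         edgelist_tsv = write_edgelist_tsv(net, path))
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# full-precision number formatting: round-trips doubles exactly and is a
# fixed point of write -> parse -> write
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == round(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    sprintf("%.17g", v)
  }, character(1))
  out
}

graphml_type <- function(v) {
  if (is.numeric(v)) "double" else "string"
}

write_graphml <- function(net, path) {
  vn <- igraph::V(net)$name
  ord <- order(vn)
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el)) {
    key <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
    eord <- order(key[, 1L], key[, 2L])
  } else eord <- integer()

  vattrs <- igraph::vertex_attr(net)
  vattrs <- vattrs[sort(setdiff(names(vattrs), "name"))]
  eattrs <- igraph::edge_attr(net)
  eattrs <- eattrs[sort(names(eattrs))]

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">")
  for (a in names(vattrs))
    lines <- c(lines, sprintf("  <key id=\"v_%s\" for=\"node\" attr.name=\"%s\" attr.type=\"%s\"/>",
                              a, xml_escape(a), graphml_type(vattrs[[a]])))
  for (a in names(eattrs))
    lines <- c(lines, sprintf("  <key id=\"e_%s\" for=\"edge\" attr.name=\"%s\" attr.type=\"%s\"/>",
                              a, xml_escape(a), graphml_type(eattrs[[a]])))
  lines <- c(lines, "  <graph edgedefault=\"undirected\">")
  for (i in ord) {
    if (length(vattrs)) {
      lines <- c(lines, sprintf("    <node id=\"%s\">", xml_escape(vn[i])))
      for (a in names(vattrs)) {
        val <- vattrs[[a]][i]
        val <- if (is.numeric(val)) fmt_num(val) else xml_escape(as.character(val))
        lines <- c(lines, sprintf("      <data key=\"v_%s\">%s</data>", a, val))
      }
      lines <- c(lines, "    </node>")
    } else {
      lines <- c(lines, sprintf("    <node id=\"%s\"/>", xml_escape(vn[i])))
    }
  }
  for (j in eord) {
    s <- pmin(el[j, 1L], el[j, 2L]); t <- pmax(el[j, 1L], el[j, 2L])
    if (length(eattrs)) {
      lines <- c(lines, sprintf("    <edge source=\"%s\" target=\"%s\">",
                                xml_escape(s), xml_escape(t)))
      for (a in names(eattrs)) {
        val <- eattrs[[a]][j]
        val <- if (is.numeric(val)) fmt_num(val) else xml_escape(as.character(val))
        lines <- c(lines, sprintf("      <data key=\"e_%s\">%s</data>", a, val))
      }
      lines <- c(lines, "    </edge>")
    } else {
      lines <- c(lines, sprintf("    <edge source=\"%s\" target=\"%s\"/>",
                                xml_escape(s), xml_escape(t)))
    }
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

read_graphml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    abort(sprintf("malformed GraphML in %s: %s", path, conditionMessage(e))))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  keys <- xml2::xml_find_all(doc, ".//g:key", ns)
  key_tab <- tibble(
    id = xml2::xml_attr(keys, "id"),
    domain = xml2::xml_attr(keys, "for"),
    name = xml2::xml_attr(keys, "attr.name"),
    type = xml2::xml_attr(keys, "attr.type")
  )
  parse_data <- function(node) {
    d <- xml2::xml_find_all(node, "./g:data", ns)
    setNames(xml2::xml_text(d), xml2::xml_attr(d, "key"))
  }
  nodes <- xml2::xml_find_all(doc, ".//g:graph/g:node", ns)
  if (length(nodes) == 0L) abort(sprintf("malformed GraphML in %s: no <node> elements", path))
  ids <- xml2::xml_attr(nodes, "id")
  if (anyNA(ids)) abort(sprintf("malformed GraphML in %s: node without id (node #%d)",
                                path, which(is.na(ids))[1L]))
  vdf <- data.frame(name = ids, stringsAsFactors = FALSE)
  ndata <- lapply(nodes, parse_data)
  for (k in key_tab$id[key_tab$domain == "node"]) {
    nm <- key_tab$name[key_tab$id == k]
    vals <- vapply(ndata, function(d) d[k] %||% NA_character_, character(1))
    vdf[[nm]] <- if (key_tab$type[key_tab$id == k] %in% c("double", "float", "int", "long"))
      suppressWarnings(as.numeric(ifelse(vals == "NA", NA, vals))) else unname(vals)
  }
  edges <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  if (length(edges)) {
    src <- xml2::xml_attr(edges, "source")
    tgt <- xml2::xml_attr(edges, "target")
    if (anyNA(src) || anyNA(tgt))
      abort(sprintf("malformed GraphML in %s: edge without endpoints (edge #%d)",
                    path, which(is.na(src) | is.na(tgt))[1L]))
    edf <- data.frame(from = src, to = tgt, stringsAsFactors = FALSE)
    edata <- lapply(edges, parse_data)
    for (k in key_tab$id[key_tab$domain == "edge"]) {
      nm <- key_tab$name[key_tab$id == k]
      vals <- vapply(edata, function(d) d[k] %||% NA_character_, character(1))
      edf[[nm]] <- if (key_tab$type[key_tab$id == k] %in% c("double", "float", "int", "long"))
        suppressWarnings(as.numeric(ifelse(vals == "NA", NA, vals))) else unname(vals)
    }
  } else {
    edf <- data.frame(from = character(), to = character())
  }
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  as_metanet(g)
}

write_pajek <- function(net, path) {
  vn <- igraph::V(net)$name
  n <- length(vn)
  x <- igraph::vertex_attr(net, "x") %||% rep(NA_real_, n)
  y <- igraph::vertex_attr(net, "y") %||% rep(NA_real_, n)
  lines <- c(
    "% Pajek network; lossy subset: id, label, coordinates, weight",
    sprintf("%% vertex index %d = \"%s\"", seq_len(n), vn),
    sprintf("*Vertices %d", n))
  has_xy <- !anyNA(x) && !anyNA(y)
  lines <- c(lines, if (has_xy)
    sprintf("%d \"%s\" %s %s", seq_len(n), vn, fmt_num(x), fmt_num(y))
    else sprintf("%d \"%s\"", seq_len(n), vn))
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- igraph::E(net)$weight %||% rep(1, nrow(el))
  lines <- c(lines, "*Edges",
             if (nrow(el)) sprintf("%d %d %s", el[, 1L], el[, 2L], fmt_num(w)))
  writeLines(lines, path)
  invisible(path)
}

read_pajek <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(trimws(lines), "%"))
  vstart <- grep("^\\*Vertices", lines[body], ignore.case = TRUE)
  estart <- grep("^\\*Edges", lines[body], ignore.case = TRUE)
  if (length(vstart) != 1L || length(estart) != 1L)
    abort(sprintf("malformed Pajek file %s: need one *Vertices and one *Edges section", path))
  vlines <- lines[body][(vstart + 1L):(estart - 1L)]
  vlines <- vlines[nzchar(trimws(vlines))]
  parse_vertex <- function(ln, lineno) {
    m <- regmatches(ln, regexec("^\\s*(\\d+)\\s+\"([^\"]*)\"(\\s+(\\S+)\\s+(\\S+))?", ln))[[1]]
    if (length(m) == 0L)
      abort(sprintf("malformed Pajek vertex line %d in %s: '%s'", lineno, path, ln))
    list(idx = as.integer(m[2]), label = m[3],
         x = if (nzchar(m[5])) as.numeric(m[5]) else NA_real_,
         y = if (length(m) >= 6 && nzchar(m[6])) as.numeric(m[6]) else NA_real_)
  }
  vs <- purrr::imap(vlines, parse_vertex)
  labels <- vapply(vs, `[[`, character(1), "label")[order(vapply(vs, `[[`, integer(1), "idx"))]
  xs <- vapply(vs, `[[`, numeric(1), "x")[order(vapply(vs, `[[`, integer(1), "idx"))]
  ys <- vapply(vs, `[[`, numeric(1), "y")[order(vapply(vs, `[[`, integer(1), "idx"))]
  elines <- lines[body][-seq_len(estart)]
  elines <- elines[nzchar(trimws(elines))]
  if (length(elines)) {
    parts <- strsplit(trimws(elines), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 2L)
    if (length(bad))
      abort(sprintf("malformed Pajek edge line %d in %s", bad[1L], path))
    ei <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    ej <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    ew <- vapply(parts, function(p) if (length(p) >= 3) as.numeric(p[3]) else 1, numeric(1))
    edf <- data.frame(from = labels[ei], to = labels[ej], weight = ew)
  } else {
    edf <- data.frame(from = character(), to = character())
  }
  vdf <- data.frame(name = labels)
  if (!anyNA(xs)) { vdf$x <- xs; vdf$y <- ys }
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  class(g) <- unique(c("metanet", class(g)))
  validate_metanet(g)
  g
}

write_edgelist_tsv <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  m <- nrow(el)
  df <- data.frame(
    source = el[, 1L], target = el[, 2L],
    r = igraph::E(net)$r %||% rep(NA_real_, m),
    sign = igraph::E(net)$sign %||% rep(NA_integer_, m),
    p_adj = igraph::E(net)$p_adj %||% rep(NA_real_, m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

read_edgelist_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(df)))
    abort(sprintf("malformed edge-list TSV %s: need source and target columns", path))
  names(df)[names(df) == "source"] <- "from"
  names(df)[names(df) == "target"] <- "to"
  if (!"r" %in% names(df)) df$r <- NA_real_
  net_from_edgelist(df[, intersect(c("from", "to", "r", "p_adj"), names(df))])
}
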