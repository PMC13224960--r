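#' Node coordinate table
#'
#' A `coors` object is a tibble with one row per node (`name`, `x`, `y`,
#' optional `group`) plus an optional `anchors` attribute recording
#' per-group anchor positions and scales. All layout functions return one.
#'
#' @param name,x,y,group coordinate columns.
#' @param anchors optional tibble (`group`, `x`, `y`, `scale`).
#' @return A `coors` tibble.
#' @export
coors <- function(name, x, y, group = NULL, anchors = NULL) {
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort("all coordinates must be finite")
  out <- tibble(name = as.character(name), x = as.numeric(x), y = as.numeric(y))
  if (!is.null(group)) out$group <- as.character(group)
  structure(out, class = c("coors", class(out)), anchors = anchors)
}

check_coors_cover <- function(coo, net) {
  if (!setequal(coo$name, igraph::V(net)$name))
    abort("layout must cover exactly the node set of the network")
  coo[match(igraph::V(net)$name, coo$name), , drop = FALSE]
}

# unit-circle convention used across the package: first node at angle 90
# degrees, counter-clockwise
circle_positions <- function(n, radius = 1, center = c(0, 0)) {
  theta <- pi / 2 + 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = center[1] + radius * cos(theta), y = center[2] + radius * sin(theta))
}

layout_registry <- function() {
  list(
    circle = function(net, ...) {
      p <- circle_positions(igraph::vcount(net))
      coors(igraph::V(net)$name, p[, 1], p[, 2])
    },
    grid = function(net, ...) {
      n <- igraph::vcount(net)
      ncol <- ceiling(sqrt(n))
      i <- seq_len(n) - 1L
      coors(igraph::V(net)$name, i %% ncol, -(i %/% ncol))
    },
    star = function(net, ...) {
      n <- igraph::vcount(net)
      if (n == 1L) return(coors(igraph::V(net)$name, 0, 0))
      p <- circle_positions(n - 1L)
      coors(igraph::V(net)$name, c(0, p[, 1]), c(0, p[, 2]))
    },
    tree = function(net, ...) {
      xy <- igraph::layout_as_tree(net)
      coors(igraph::V(net)$name, xy[, 1], xy[, 2])
    },
    fr = function(net, ...) {
      xy <- igraph::layout_with_fr(net, ...)
      coors(igraph::V(net)$name, xy[, 1], xy[, 2])
    },
    kk = function(net, ...) {
      xy <- igraph::layout_with_kk(net, ...)
      coors(igraph::V(net)$name, xy[, 1], xy[, 2])
    },
    random = function(net, ...) {
      xy <- igraph::layout_randomly(net)
      coors(igraph::V(net)$name, xy[, 1], xy[, 2])
    }
  )
}

#' Compute node coordinates
#'
#' Unified layout interface. Deterministic conventions: `circle` places
#' nodes on the unit circle starting at angle 90 degrees and proceeding
#' counter-clockwise; `grid` fills a row-major integer lattice; `star`
#' puts the first node at the origin. Stochastic algorithms (`fr`, `kk`,
#' `random`) are bit-reproducible given `seed`.
#'
#' @param net a [as_metanet()] network.
#' @param algorithm a registry name: one of
#'   `circle`, `grid`, `star`, `tree`, `fr`, `kk`, `random`.
#' @param ... passed to the underlying algorithm.
#' @param seed optional integer seed for stochastic algorithms.
#' @return A [coors()] table covering every node.
#' @export
c_net_layout <- function(net, algorithm = "fr", ..., seed = NULL) {
  stopifnot(inherits(net, "metanet"))
  reg <- layout_registry()
  if (!is_string(algorithm) || !algorithm %in% names(reg))
    abort(sprintf("unknown layout algorithm '%s'; registry: %s",
                  algorithm, paste(names(reg), collapse = ", ")))
  local_seed(seed, reg[[algorithm]](net, ...))
}

#' Place node groups on the sides of a regular polygon
#'
#' The polygon is a regular `n_sides`-gon inscribed in the unit circle
#' with vertex 1 at angle 90 degrees (counter-clockwise). The nodes of the
#' g-th group (groups in sorted label order) are spaced evenly strictly
#' inside side g: k nodes sit at fractions `1/(k+1), ..., k/(k+1)` of the
#' side, so vertices are never occupied.
#'
#' @param net a [as_metanet()] network.
#' @param groups named character vector (node -> group label), or the name
#'   of a node attribute.
#' @param n_sides number of polygon sides (default: number of groups).
#' @return A [coors()] table with the `group` column filled.
#' @export
as_polygon <- function(net, groups, n_sides = NULL) {
  g <- resolve_groups(net, groups)
  labs <- sort(unique(g))
  n_sides <- n_sides %||% length(labs)
  if (length(labs) > n_sides)
    abort(sprintf("%d groups but only %d sides", length(labs), n_sides))
  verts <- circle_positions(n_sides)
  nodes <- igraph::V(net)$name
  out <- vector("list", length(labs))
  for (gi in seq_along(labs)) {
    members <- nodes[g == labs[gi]]
    a <- verts[gi, ]
    b <- verts[(gi %% n_sides) + 1L, ]
    k <- length(members)
    f <- seq_len(k) / (k + 1)
    out[[gi]] <- tibble(name = members,
                        x = a[1] + f * (b[1] - a[1]),
                        y = a[2] + f * (b[2] - a[2]),
                        group = labs[gi])
  }
  df <- dplyr::bind_rows(out)
  df <- df[match(nodes, df$name), ]
  coors(df$name, df$x, df$y, df$group)
}

#' Place node groups on circles arranged as a regular polygon
#'
#' Group g's nodes are laid on a circle of radius 0.3 (the package's inner
#' layout scale) centered at vertex g of a regular `n_polygons`-gon of
#' unit circumradius (vertex 1 at 90 degrees).
#'
#' @inheritParams as_polygon
#' @param n_polygons number of group circles (default: number of groups).
#' @return A [coors()] table; anchors record the group circle centers.
#' @export
as_polycircle <- function(net, groups, n_polygons = NULL) {
  g <- resolve_groups(net, groups)
  labs <- sort(unique(g))
  n_polygons <- n_polygons %||% length(labs)
  if (length(labs) > n_polygons)
    abort(sprintf("%d groups but only %d polygon vertices", length(labs), n_polygons))
  centers <- circle_positions(n_polygons)
  nodes <- igraph::V(net)$name
  out <- vector("list", length(labs))
  for (gi in seq_along(labs)) {
    members <- nodes[g == labs[gi]]
    p <- circle_positions(length(members), radius = 0.3, center = centers[gi, ])
    out[[gi]] <- tibble(name = members, x = p[, 1], y = p[, 2], group = labs[gi])
  }
  df <- dplyr::bind_rows(out)
  df <- df[match(nodes, df$name), ]
  coors(df$name, df$x, df$y, df$group,
        anchors = tibble(group = labs, x = centers[seq_along(labs), 1],
                         y = centers[seq_along(labs), 2], scale = 0.3))
}

resolve_groups <- function(net, groups) {
  nodes <- igraph::V(net)$name
  if (is_string(groups) && !is.null(igraph::vertex_attr(net, groups)))
    return(as.character(igraph::vertex_attr(net, groups)))
  g <- groups[nodes]
  if (anyNA(g)) abort("every node needs a group label")
  as.character(g)
}

#' Constrain a layout to a polygon
#'
#' Places nodes inside a user-defined simple polygon or along its
#' boundary. `uniform_inside` samples uniformly by area: the polygon is
#' ear-clip triangulated, a triangle is chosen with probability
#' proportional to its area and a point drawn uniformly in it via
#' barycentric coordinates (robust for concave shapes, no rejection).
#' `random_inside` uses bounding-box rejection sampling. `on_edges` places
#' nodes at equal arc-length steps around the boundary starting from the
#' first vertex.
#'
#' @param net a [as_metanet()] network.
#' @param polygon two-column matrix or data frame (`x`, `y`) of ring
#'   vertices; the ring may be open or closed, convex or concave, but must
#'   be simple (non-self-intersecting).
#' @param mode `"uniform_inside"`, `"random_inside"` or `"on_edges"`.
#' @param seed integer seed for the sampling modes.
#' @return A [coors()] table.
#' @export
spatstat_layout <- function(net, polygon,
                            mode = c("uniform_inside", "random_inside", "on_edges"),
                            seed = NULL) {
  stopifnot(inherits(net, "metanet"))
  mode <- match.arg(mode)
  ring <- as_ring(polygon)
  if (!polygon_is_simple(ring)) abort("polygon must be simple (no self-intersections)")
  n <- igraph::vcount(net)
  nodes <- igraph::V(net)$name
  if (mode == "on_edges") {
    seg <- rbind(ring, ring[1L, ])
    lens <- sqrt(diff(seg[, 1L])^2 + diff(seg[, 2L])^2)
    per <- sum(lens)
    pos <- per * (seq_len(n) - 1L) / n
    cum <- c(0, cumsum(lens))
    si <- findInterval(pos, cum, rightmost.closed = TRUE)
    f <- (pos - cum[si]) / lens[si]
    return(coors(nodes,
                 seg[si, 1L] + f * (seg[si + 1L, 1L] - seg[si, 1L]),
                 seg[si, 2L] + f * (seg[si + 1L, 2L] - seg[si, 2L])))
  }
  if (abs(polygon_area(ring)) < 1e-12) abort("zero-area polygon")
  local_seed(seed, {
    if (mode == "uniform_inside") {
      tris <- ear_clip(ring)
      areas <- vapply(tris, function(tr) abs(polygon_area(tr)), numeric(1))
      ti <- sample.int(length(tris), n, replace = TRUE, prob = areas)
      u1 <- runif(n); u2 <- runif(n)
      flip <- u1 + u2 > 1
      u1[flip] <- 1 - u1[flip]; u2[flip] <- 1 - u2[flip]
      pts <- t(vapply(seq_len(n), function(k) {
        tr <- tris[[ti[k]]]
        tr[1L, ] + u1[k] * (tr[2L, ] - tr[1L, ]) + u2[k] * (tr[3L, ] - tr[1L, ])
      }, numeric(2)))
      coors(nodes, pts[, 1L], pts[, 2L])
    } else {
      bb <- apply(ring, 2L, range)
      xs <- numeric(n); ys <- numeric(n); got <- 0L; guard <- 0L
      while (got < n) {
        guard <- guard + 1L
        if (guard > 10000L) abort("rejection sampling failed to fill the polygon")
        m <- (n - got) * 4L
        cx <- runif(m, bb[1L, 1L], bb[2L, 1L])
        cy <- runif(m, bb[1L, 2L], bb[2L, 2L])
        keep <- point_in_polygon(cx, cy, ring)
        take <- min(sum(keep), n - got)
        if (take > 0L) {
          xs[got + seq_len(take)] <- cx[keep][seq_len(take)]
          ys[got + seq_len(take)] <- cy[keep][seq_len(take)]
          got <- got + take
        }
      }
      coors(nodes, xs, ys)
    }
  })
}

#' Grouped layout with per-group anchors, scales and inner algorithms
#'
#' Lays out each group independently with its own inner algorithm, centers
#' the group on its anchor and scales it. Because each group is an exact
#' similarity transform of its inner layout, compositions nest: a
#' `g_layout()` result used as one group of a larger call keeps its inner
#' relative geometry.
#'
#' @param net a [as_metanet()] network.
#' @param groups named vector (node -> group) or node attribute name.
#' @param spec data frame with one row per group: columns `group`, `x`,
#'   `y` (anchor), `scale`, `algorithm` (a [c_net_layout()] registry name).
#' @param seed optional seed applied to stochastic inner algorithms.
#' @return A [coors()] table; `attr(, "anchors")` records the spec.
#' @export
g_layout <- function(net, groups, spec, seed = NULL) {
  stopifnot(inherits(net, "metanet"))
  g <- resolve_groups(net, groups)
  spec <- as_tibble(spec)
  need <- c("group", "x", "y", "scale", "algorithm")
  if (!all(need %in% names(spec)))
    abort("`spec` needs columns group, x, y, scale, algorithm")
  missing_spec <- setdiff(unique(g), as.character(spec$group))
  if (length(missing_spec))
    abort(sprintf("no spec row for group(s): %s", paste(missing_spec, collapse = ", ")))
  nodes <- igraph::V(net)$name
  out <- vector("list", nrow(spec))
  local_seed(seed, {
    for (i in seq_len(nrow(spec))) {
      members <- nodes[g == as.character(spec$group[i])]
      if (length(members) == 0L) next
      sub <- igraph::induced_subgraph(net, members)
      class(sub) <- unique(c("metanet", class(sub)))
      inner <- c_net_layout(sub, algorithm = spec$algorithm[i])
      cx <- mean(inner$x); cy <- mean(inner$y)
      out[[i]] <- tibble(
        name = inner$name,
        x = spec$x[i] + spec$scale[i] * (inner$x - cx),
        y = spec$y[i] + spec$scale[i] * (inner$y - cy),
        group = as.character(spec$group[i]))
    }
  })
  df <- dplyr::bind_rows(out)
  df <- df[match(nodes, df$name), ]
  coors(df$name, df$x, df$y, df$group,
        anchors = spec[, c("group", "x", "y", "scale")])
}

#' Circle-packing layout of modules
#'
#' Each module occupies a circle of radius proportional to the square root
#' of its size (so circle area tracks module size). Circles are packed
#' greedily in descending size order: the largest sits at the origin and
#' each next circle is placed at the first non-overlapping position along
#' an Archimedean spiral. Nodes are laid on an inner circle at 0.8 times
#' the module radius.
#'
#' @param net a [as_metanet()] network.
#' @param modules a `module_assignment` (or data frame with `node`,
#'   `module`).
#' @return A [coors()] table with `group` = module id; anchors record the
#'   module circle centers and radii.
#' @export
g_layout_circlepack <- function(net, modules) {
  stopifnot(inherits(net, "metanet"))
  memb <- modules$module[match(igraph::V(net)$name, modules$node)]
  if (anyNA(memb)) abort("`modules` must cover every node of `net`")
  if (length(memb) == 0L) abort("empty module set")
  sizes <- sort(table(memb), decreasing = TRUE)
  ids <- names(sizes)
  radii <- sqrt(as.numeric(sizes))
  centers <- matrix(0, length(ids), 2L)
  if (length(ids) > 1L) {
    step <- min(radii) / 20
    for (i in 2:length(ids)) {
      theta <- 0
      repeat {
        theta <- theta + step / (1 + theta)
        cand <- (radii[1L] + radii[i]) * theta / (2 * pi) * c(cos(theta), sin(theta))
        ok <- all(sqrt(colSums((t(centers[seq_len(i - 1L), , drop = FALSE]) - cand)^2)) >=
                    radii[seq_len(i - 1L)] + radii[i] - 1e-12)
        if (ok) { centers[i, ] <- cand; break }
      }
    }
  }
  nodes <- igraph::V(net)$name
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    members <- nodes[as.character(memb) == ids[i]]
    p <- circle_positions(length(members), radius = 0.8 * radii[i], center = centers[i, ])
    out[[i]] <- tibble(name = members, x = p[, 1L], y = p[, 2L], group = ids[i])
  }
  df <- dplyr::bind_rows(out)
  df <- df[match(nodes, df$name), ]
  coors(df$name, df$x, df$y, df$group,
        anchors = tibble(group = ids, x = centers[, 1L], y = centers[, 2L],
                         scale = radii))
}

#' Pseudo-3D multi-layer layout
#'
#' Lays each layer out in 2-D (inner `circle` convention by default), then
#' applies the affine pseudo-3D map
#' `(x, y) -> (x + y*cos(alpha), y*sin(alpha) + layer_index * dz)` with
#' layers stacked in sorted label order (index 0 at the bottom).
#'
#' @param net a [as_metanet()] network.
#' @param layers named vector (node -> layer) or node attribute name.
#' @param dz vertical distance between consecutive layers (> 0).
#' @param alpha shear angle in degrees; 90 means no horizontal shear.
#' @param inner inner layout algorithm name.
#' @param seed optional seed for stochastic inner layouts.
#' @return A [coors()] table with `group` = layer label.
#' @export
g_layout_multi_layer <- function(net, layers, dz = 1, alpha = 60,
                                 inner = "circle", seed = NULL) {
  stopifnot(inherits(net, "metanet"))
  if (!is.numeric(dz) || dz <= 0) abort("`dz` must be > 0")
  g <- resolve_groups(net, layers)
  labs <- sort(unique(g))
  a <- deg2rad(alpha)
  nodes <- igraph::V(net)$name
  out <- vector("list", length(labs))
  local_seed(seed, {
    for (i in seq_along(labs)) {
      members <- nodes[g == labs[i]]
      sub <- igraph::induced_subgraph(net, members)
      class(sub) <- unique(c("metanet", class(sub)))
      inner_coo <- c_net_layout(sub, algorithm = inner)
      out[[i]] <- tibble(
        name = inner_coo$name,
        x = inner_coo$x + inner_coo$y * cos(a),
        y = inner_coo$y * sin(a) + (i - 1L) * dz,
        group = labs[i])
    }
  })
  df <- dplyr::bind_rows(out)
  df <- df[match(nodes, df$name), ]
  coors(df$name, df$x, df$y, df$group)
}

#' Affine transforms of a coordinate table
#'
#' Exact affine maps applied about the layout centroid unless `origin` is
#' given: `scale` (factor != 0), `rotate` (angle degrees,
#' counter-clockwise), `mirror_x` (flip y), `mirror_y` (flip x),
#' `shear_pseudo3d` (`(x, y) -> (x + y*cos(alpha), y*sin(alpha))`).
#'
#' @param coo a [coors()] table.
#' @param op one of `"scale"`, `"rotate"`, `"mirror_x"`, `"mirror_y"`,
#'   `"shear_pseudo3d"`.
#' @param factor scale factor (op = scale).
#' @param angle rotation/shear angle in degrees.
#' @param origin optional `c(x, y)` fixed point; default the centroid.
#' @return The transformed [coors()] table.
#' @export
transform_coors <- function(coo, op = c("scale", "rotate", "mirror_x", "mirror_y",
                                        "shear_pseudo3d"),
                            factor = 1, angle = 0, origin = NULL) {
  stopifnot(inherits(coo, "coors"))
  op <- match.arg(op)
  o <- origin %||% c(mean(coo$x), mean(coo$y))
  x <- coo$x - o[1]; y <- coo$y - o[2]
  if (op == "scale") {
    if (factor == 0) abort("scale factor must be non-zero")
    x <- factor * x; y <- factor * y
  } else if (op == "rotate") {
    a <- deg2rad(angle)
    xr <- cos(a) * x - sin(a) * y
    y <- sin(a) * x + cos(a) * y
    x <- xr
  } else if (op == "mirror_x") {
    y <- -y
  } else if (op == "mirror_y") {
    x <- -x
  } else {
    a <- deg2rad(angle)
    x <- x + y * cos(a)
    y <- y * sin(a)
  }
  out <- coo
  out$x <- x + o[1]
  out$y <- y + o[2]
  out
}

#' Write a coordinate table as TSV
#'
#' Columns `node`, `x`, `y`, `group`.
#'
#' @param coo a [coors()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coors_tsv <- function(coo, path) {
  stopifnot(inherits(coo, "coors"))
  df <- data.frame(node = coo$name, x = coo$x, y = coo$y,
                   group = if ("group" %in% names(coo)) coo$group else NA)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Plot a network with a layout
#'
#' Minimal ggplot rendering: edges as segments (solid positive, dashed
#' negative), nodes as points coloured by `colour_by` when present.
#'
#' @param object a [as_metanet()] network.
#' @param coo a [coors()] table (default: circle layout).
#' @param colour_by node attribute for the colour aesthetic.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.metanet <- function(object, coo = NULL, colour_by = NULL, ...) {
  coo <- coo %||% c_net_layout(object, "circle")
  coo <- check_coors_cover(coo, object)
  nd <- net_nodes(object)
  nd <- dplyr::left_join(nd, as_tibble(coo)[, c("name", "x", "y")], by = "name")
  ed <- net_edges(object)
  p <- ggplot2::ggplot()
  if (nrow(ed)) {
    ed$x <- coo$x[match(ed$from, coo$name)]
    ed$y <- coo$y[match(ed$from, coo$name)]
    ed$xend <- coo$x[match(ed$to, coo$name)]
    ed$yend <- coo$y[match(ed$to, coo$name)]
    ed$assoc <- if ("sign" %in% names(ed)) ifelse(ed$sign >= 0, "positive", "negative")
      else "positive"
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                   linetype = .data$assoc),
      colour = "grey60")
  }
  if (!is.null(colour_by) && colour_by %in% names(nd)) {
    p <- p + ggplot2::geom_point(data = nd,
                                 ggplot2::aes(.data$x, .data$y,
                                              colour = .data[[colour_by]]), size = 2)
  } else {
    p <- p + ggplot2::geom_point(data = nd, ggplot2::aes(.data$x, .data$y), size = 2)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_void()
}
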