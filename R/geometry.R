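# 2-D polygon primitives used by the constrained layouts. Polygons are
# simple rings given as a two-column matrix (or data frame with x, y),
# open (last vertex != first); orientation is normalized internally.

as_ring <- function(polygon) {
  if (is.data.frame(polygon)) polygon <- as.matrix(polygon[, c("x", "y")])
  if (!is.matrix(polygon) || ncol(polygon) != 2L || nrow(polygon) < 3L)
    abort("polygon must be a matrix/data frame of at least 3 (x, y) vertices")
  storage.mode(polygon) <- "double"
  if (any(!is.finite(polygon))) abort("polygon vertices must be finite")
  # drop a closing vertex if the ring was given closed
  n <- nrow(polygon)
  if (all(polygon[1L, ] == polygon[n, ])) polygon <- polygon[-n, , drop = FALSE]
  if (nrow(polygon) < 3L) abort("polygon must have at least 3 distinct vertices")
  polygon
}

# signed area (shoelace); positive for counter-clockwise rings
polygon_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_is_simple <- function(ring) {
  n <- nrow(ring)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(ring[i, ], ring[idx(i + 1L), ],
                             ring[j, ], ring[idx(j + 1L), ])) return(FALSE)
    }
  }
  TRUE
}

# ray-casting test, TRUE for interior points; `on_boundary` tolerance
# accepts points within eps of an edge
point_in_polygon <- function(px, py, ring, eps = 1e-9) {
  n <- nrow(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  out <- logical(length(px))
  for (k in seq_along(px)) {
    # boundary check: distance to each edge segment
    dx <- xn - x; dy <- yn - y
    tt <- pmin(pmax(((px[k] - x) * dx + (py[k] - y) * dy) / (dx^2 + dy^2), 0), 1)
    dist2 <- (x + tt * dx - px[k])^2 + (y + tt * dy - py[k])^2
    if (min(dist2) <= eps^2) { out[k] <- TRUE; next }
    crossings <- ((y > py[k]) != (yn > py[k])) &
      (px[k] < (xn - x) * (py[k] - y) / (yn - y) + x)
    out[k] <- (sum(crossings) %% 2L) == 1L
  }
  out
}

# ear-clipping triangulation of a simple polygon; returns a list of
# 3 x 2 vertex matrices
ear_clip <- function(ring) {
  if (polygon_area(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  idx <- seq_len(nrow(ring))
  tris <- list()
  cross_z <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  in_tri <- function(p, a, b, c) {
    d1 <- cross_z(a, b, p); d2 <- cross_z(b, c, p); d3 <- cross_z(c, a, p)
    !(any(c(d1, d2, d3) < 0) && any(c(d1, d2, d3) > 0))
  }
  guard <- 0L
  while (length(idx) > 3L) {
    guard <- guard + 1L
    if (guard > 10000L) abort("triangulation failed (is the polygon simple?)")
    n <- length(idx)
    clipped <- FALSE
    for (i in seq_len(n)) {
      ia <- idx[((i - 2L) %% n) + 1L]; ib <- idx[i]; ic <- idx[(i %% n) + 1L]
      a <- ring[ia, ]; b <- ring[ib, ]; c <- ring[ic, ]
      if (cross_z(a, b, c) <= 1e-14) next    # reflex or collinear
      others <- setdiff(idx, c(ia, ib, ic))
      if (any(vapply(others, function(o) in_tri(ring[o, ], a, b, c), logical(1)))) next
      tris[[length(tris) + 1L]] <- rbind(a, b, c)
      idx <- idx[idx != ib]
      clipped <- TRUE
      break
    }
    if (!clipped) abort("triangulation failed (degenerate polygon)")
  }
  tris[[length(tris) + 1L]] <- ring[idx, , drop = FALSE]
  tris
}
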