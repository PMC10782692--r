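# Planar geometry helpers for mask/cell overlap. All coordinates are WSI
# pixels. Polygons are 2-column matrices of vertices, implicitly closed.

polygon_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(xy[j, 1] * xy[, 2] - xy[, 1] * xy[j, 2])) / 2
}

# Proper-crossing test for two closed segments, shared endpoints allowed.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# A polygon is simple when no two non-adjacent edges properly cross.
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  nxt <- c(seq_len(n)[-1], 1)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (j == i || j == nxt[i] || nxt[j] == i) next
      if (segments_cross(xy[i, ], xy[nxt[i], ], xy[j, ], xy[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Sutherland-Hodgman clip of a polygon against the axis-aligned rectangle
# [x0,x1] x [y0,y1]. Exact for simple polygons clipped by a convex window.
clip_polygon_rect <- function(xy, x0, y0, x1, y1) {
  clip_halfplane <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    prev <- pts[n, ]
    prev_in <- inside(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- inside(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
      prev <- cur
      prev_in <- cur_in
    }
    out
  }
  ix <- function(p, q, val, axis) {
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  pts <- xy
  pts <- clip_halfplane(pts, function(p) p[1] >= x0, function(p, q) ix(p, q, x0, 1))
  pts <- clip_halfplane(pts, function(p) p[1] <= x1, function(p, q) ix(p, q, x1, 1))
  pts <- clip_halfplane(pts, function(p) p[2] >= y0, function(p, q) ix(p, q, y0, 2))
  pts <- clip_halfplane(pts, function(p) p[2] <= y1, function(p, q) ix(p, q, y1, 2))
  pts
}

# Even-odd ray-casting point-in-polygon; boundary points count as inside.
points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Fraction of the rectangle [x0,x1] x [y0,y1] covered by the union of the
# mask's excluded regions. Single-polygon overlaps are exact (clip + shoelace);
# unions of several overlapping polygons fall back to midpoint sampling on an
# n_sub x n_sub subgrid, since exclusion polygons may overlap.
excluded_fraction_rect <- function(mask, x0, y0, x1, y1, n_sub = 32) {
  cell_area <- (x1 - x0) * (y1 - y0)
  if (cell_area <= 0) return(0)
  if (is.null(mask)) return(0)
  if (mask$type == "raster") {
    s <- mask$scale_px
    rr <- seq(floor(y0 / s) + 1, ceiling(y1 / s))
    cc <- seq(floor(x0 / s) + 1, ceiling(x1 / s))
    rr <- rr[rr >= 1 & rr <= nrow(mask$raster)]
    cc <- cc[cc >= 1 & cc <= ncol(mask$raster)]
    if (length(rr) == 0 || length(cc) == 0) return(0)
    return(mean(mask$raster[rr, cc, drop = FALSE]))
  }
  touching <- purrr::keep(mask$polygons, function(p) {
    clip <- clip_polygon_rect(p$xy, x0, y0, x1, y1)
    nrow(clip) >= 3 && polygon_area(clip) > 0
  })
  if (length(touching) == 0) return(0)
  if (length(touching) == 1) {
    clip <- clip_polygon_rect(touching[[1]]$xy, x0, y0, x1, y1)
    return(min(1, polygon_area(clip) / cell_area))
  }
  gx <- x0 + (seq_len(n_sub) - 0.5) * (x1 - x0) / n_sub
  gy <- y0 + (seq_len(n_sub) - 0.5) * (y1 - y0) / n_sub
  px <- rep(gx, times = n_sub)
  py <- rep(gy, each = n_sub)
  covered <- logical(length(px))
  for (p in touching) {
    covered <- covered | points_in_polygon(px, py, p$xy)
  }
  mean(covered)
}
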