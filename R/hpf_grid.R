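#' High-power-field grid specification
#'
#' Describes the square tiling of the slide plane into high-power fields
#' (HPFs). Under the defaults, one cell is 1600 px x 0.25 um/px = 400 um on a
#' side, i.e. the standard 0.16 mm^2 HPF. The grid anchor is a free parameter:
#' `origin_offset` shifts the tiling within one cell edge, and
#' [origin_shift_scan()] treats it as a sensitivity parameter.
#'
#' @param hpf_edge_px Cell edge in pixels (> 0).
#' @param microns_per_px Scanner resolution, micrometres per pixel (> 0).
#' @param origin_offset Length-2 numeric `(dx, dy)` in pixels, each in
#'   `[0, hpf_edge_px)`.
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' grid_spec()                      # the standard 0.16 mm^2 HPF
#' grid_spec(origin_offset = c(800, 0))
grid_spec <- function(hpf_edge_px = 1600, microns_per_px = 0.25,
                      origin_offset = c(0, 0)) {
  if (hpf_edge_px <= 0 || microns_per_px <= 0) {
    abort("hpf_edge_px and microns_per_px must be positive",
          class = "mitoquant_parameter_error")
  }
  origin_offset <- as.numeric(origin_offset)
  if (length(origin_offset) != 2 || any(origin_offset < 0) ||
      any(origin_offset >= hpf_edge_px)) {
    abort("origin_offset must be (dx, dy) with 0 <= d < hpf_edge_px",
          class = "mitoquant_parameter_error")
  }
  structure(list(hpf_edge_px = hpf_edge_px, microns_per_px = microns_per_px,
                 origin_offset = origin_offset, n_rows = NA_integer_,
                 n_cols = NA_integer_),
            class = "grid_spec")
}

#' Shift the grid origin
#'
#' Returns a copy of `spec` with a new `origin_offset`. Re-binning under the
#' shifted spec follows the same half-open floor rule, so shifting by a full
#' edge is a pure translation of the tiling.
#'
#' @param spec A [grid_spec()].
#' @param dx,dy Offsets in pixels, each in `[0, hpf_edge_px)`.
#' @return A new `grid_spec`.
#' @export
shift_origin <- function(spec, dx, dy) {
  if (dx < 0 || dy < 0 || dx >= spec$hpf_edge_px || dy >= spec$hpf_edge_px) {
    abort("origin shift must satisfy 0 <= d < hpf_edge_px",
          class = "mitoquant_parameter_error")
  }
  spec$origin_offset <- c(dx, dy)
  spec
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> edge ", x$hpf_edge_px, " px (",
      x$hpf_edge_px * x$microns_per_px, " um), offset (",
      x$origin_offset[1], ", ", x$origin_offset[2], ")\n", sep = "")
  invisible(x)
}

mask_bbox <- function(mask) {
  if (is.null(mask)) return(NULL)
  if (mask$type == "raster") {
    if (!any(mask$raster)) return(NULL)
    return(c(0, 0, ncol(mask$raster) * mask$scale_px, nrow(mask$raster) * mask$scale_px))
  }
  if (length(mask$polygons) == 0) return(NULL)
  xs <- unlist(purrr::map(mask$polygons, ~ .x$xy[, 1]))
  ys <- unlist(purrr::map(mask$polygons, ~ .x$xy[, 2]))
  c(min(xs), min(ys), max(xs), max(ys))
}

#' Bin mitosis points into an HPF grid
#'
#' Partitions the plane into half-open square cells
#' `[dx + k*edge, dx + (k+1)*edge)` and assigns each point to the unique cell
#' containing it, so a point on a shared boundary belongs to exactly one cell
#' ("without overlapping" tiling). The grid extent is the bounding box of the
#' points (and mask, when given) rounded out to whole cells; points whose
#' shifted coordinate is negative extend the grid rather than being dropped.
#'
#' Cells overlapping excluded mask area beyond `1 - min_fraction` of their area
#' are marked ineligible. Points in ineligible cells stay in the count matrix
#' (they are reported in totals) but contribute to no hotspot quantity.
#'
#' @param points Data frame of points (columns `x`, `y`); may be empty.
#' @param spec A [grid_spec()].
#' @param mask A `region_mask` or `NULL`.
#' @param min_fraction Minimum unexcluded area fraction for eligibility.
#' @return An object of class `hpf_grid` with fields `counts` (integer matrix),
#'   `eligible` (logical matrix), `spec`, `row0`/`col0` (absolute index of the
#'   first matrix row/column), `n_points`, `n_points_ineligible`.
#' @export
#' @examples
#' pts <- data.frame(x = c(10, 1700, 1705), y = c(10, 20, 30))
#' g <- make_grid(pts, grid_spec())
#' as_tibble(g)
make_grid <- function(points, spec = grid_spec(), mask = NULL,
                      min_fraction = 0.99) {
  points <- as_point_tibble(points)
  if (min_fraction < 0 || min_fraction > 1) {
    abort("min_fraction must be in [0, 1]", class = "mitoquant_parameter_error")
  }
  edge <- spec$hpf_edge_px
  dx <- spec$origin_offset[1]
  dy <- spec$origin_offset[2]

  col_idx <- floor((points$x - dx) / edge)
  row_idx <- floor((points$y - dy) / edge)

  bb <- mask_bbox(mask)
  lo_r <- min(0, row_idx, if (!is.null(bb)) floor((bb[2] - dy) / edge))
  lo_c <- min(0, col_idx, if (!is.null(bb)) floor((bb[1] - dx) / edge))
  hi_r <- max(0, row_idx, if (!is.null(bb)) floor((bb[4] - dy) / edge))
  hi_c <- max(0, col_idx, if (!is.null(bb)) floor((bb[3] - dx) / edge))

  n_rows <- as.integer(hi_r - lo_r + 1)
  n_cols <- as.integer(hi_c - lo_c + 1)
  counts <- matrix(0L, n_rows, n_cols)
  if (nrow(points) > 0) {
    ij <- cbind(row_idx - lo_r + 1, col_idx - lo_c + 1)
    tab <- table(factor(ij[, 1], levels = seq_len(n_rows)),
                 factor(ij[, 2], levels = seq_len(n_cols)))
    counts <- matrix(as.integer(tab), n_rows, n_cols)
  }
  spec$n_rows <- n_rows
  spec$n_cols <- n_cols
  eligible <- compute_eligibility(spec, mask, min_fraction,
                                  row0 = as.integer(lo_r), col0 = as.integer(lo_c))
  structure(list(counts = counts, eligible = eligible, spec = spec,
                 row0 = as.integer(lo_r), col0 = as.integer(lo_c),
                 n_points = nrow(points),
                 n_points_ineligible = sum(counts[!eligible])),
            class = "hpf_grid")
}

#' Per-cell eligibility from an exclusion mask
#'
#' A cell is eligible iff the fraction of its area not covered by any excluded
#' region is at least `min_fraction`. With the default `min_fraction = 0.99` a
#' cell must be essentially mask-free; the threshold is configurable because
#' partial-overlap handling at region borders is a modelling choice.
#'
#' @param spec A [grid_spec()] with `n_rows`/`n_cols` set (as inside a grid).
#' @param mask A `region_mask` or `NULL` (everything eligible).
#' @param min_fraction Minimum unexcluded fraction, in `[0, 1]`.
#' @param row0,col0 Absolute index of the first matrix row/column.
#' @return Logical `n_rows` x `n_cols` matrix.
#' @export
compute_eligibility <- function(spec, mask, min_fraction = 0.99,
                                row0 = 0L, col0 = 0L) {
  if (min_fraction < 0 || min_fraction > 1) {
    abort("min_fraction must be in [0, 1]", class = "mitoquant_parameter_error")
  }
  n_rows <- spec$n_rows
  n_cols <- spec$n_cols
  if (is.na(n_rows) || is.na(n_cols)) {
    abort("spec must carry grid dimensions (n_rows, n_cols)",
          class = "mitoquant_parameter_error")
  }
  elig <- matrix(TRUE, n_rows, n_cols)
  if (is.null(mask)) return(elig)
  if (mask$type == "polygons" && length(mask$polygons) == 0) return(elig)
  if (mask$type == "raster" && !any(mask$raster)) return(elig)
  edge <- spec$hpf_edge_px
  dx <- spec$origin_offset[1]
  dy <- spec$origin_offset[2]
  bb <- mask_bbox(mask)
  for (i in seq_len(n_rows)) {
    y0 <- dy + (row0 + i - 1) * edge
    y1 <- y0 + edge
    if (!is.null(bb) && (y1 <= bb[2] || y0 >= bb[4])) next
    for (j in seq_len(n_cols)) {
      x0 <- dx + (col0 + j - 1) * edge
      x1 <- x0 + edge
      if (!is.null(bb) && (x1 <= bb[1] || x0 >= bb[3])) next
      frac_excl <- excluded_fraction_rect(mask, x0, y0, x1, y1)
      elig[i, j] <- (1 - frac_excl) >= min_fraction
    }
  }
  elig
}

#' @export
print.hpf_grid <- function(x, ...) {
  cat("<hpf_grid> ", nrow(x$counts), " x ", ncol(x$counts), " cells, ",
      x$n_points, " point(s), ", sum(x$eligible), " eligible cell(s)",
      if (x$n_points_ineligible > 0)
        paste0(" [", x$n_points_ineligible, " point(s) in ineligible cells]"),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tabulate an HPF grid
#'
#' @param x An `hpf_grid`.
#' @param ... Unused.
#' @return A tibble with one row per cell: `row`, `col` (absolute cell
#'   indices), `count`, `eligible`.
#' @method as_tibble hpf_grid
#' @export
as_tibble.hpf_grid <- function(x, ...) {
  nr <- nrow(x$counts)
  nc <- ncol(x$counts)
  tibble::tibble(
    row = rep(seq_len(nr) + x$row0 - 1L, times = nc),
    col = rep(seq_len(nc) + x$col0 - 1L, each = nr),
    count = as.integer(x$counts),
    eligible = as.logical(x$eligible)
  )
}

#' Build an HPF grid directly from matrices
#'
#' Constructs an `hpf_grid` from a per-cell count matrix and an optional
#' eligibility matrix, bypassing point binning. Useful for small worked
#' examples and for feeding the quantifiers a known configuration.
#'
#' @param counts Integer matrix of per-cell mitosis counts, `counts[row, col]`.
#' @param eligible Logical matrix of the same shape; default all `TRUE`.
#' @param spec A [grid_spec()]; dimensions are taken from `counts`.
#' @return An object of class `hpf_grid`.
#' @export
#' @examples
#' g <- hpf_grid(matrix(c(3, 0, 1, 2, 9, 1, 0, 4, 1), 3, byrow = TRUE))
#' dfs_max_path(g, L = 3)
hpf_grid <- function(counts, eligible = NULL, spec = grid_spec()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(eligible)) eligible <- matrix(TRUE, nrow(counts), ncol(counts))
  stopifnot(all(dim(counts) == dim(eligible)))
  spec$n_rows <- nrow(counts)
  spec$n_cols <- ncol(counts)
  structure(list(counts = counts, eligible = eligible, spec = spec,
                 row0 = 0L, col0 = 0L, n_points = sum(counts),
                 n_points_ineligible = sum(counts[!eligible])),
            class = "hpf_grid")
}
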