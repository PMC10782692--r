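#' Read mitosis point annotations
#'
#' Reads point annotations in whole-slide-image pixel coordinates from either a
#' CSV file (columns `x_px`, `y_px` and optionally `annotator`, `label`; plain
#' `x`/`y` headers are also accepted) or a GeoJSON `FeatureCollection` of
#' `Point` features in the QuPath dialect, where the class name is carried in
#' `properties$classification$name` or `properties$label`.
#'
#' Coordinates are 0-based pixels in the scanner frame with the y axis pointing
#' downward. They are preserved exactly; no rounding or reprojection happens on
#' read.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (default, by file extension), `"csv"` or `"geojson"`.
#' @return A tibble with columns `x`, `y` (double, pixels), `annotator` and
#'   `label` (character, `NA` when absent), one row per point.
#' @seealso [write_points()] for the inverse, [read_mask()] for region masks.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines("x_px,y_px,annotator\n100,200,r1", f)
#' read_points(f)
read_points <- function(path, format = c("auto", "csv", "geojson")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path), class = "mitoquant_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) "geojson" else "csv"
  }
  pts <- if (format == "csv") read_points_csv(path) else read_points_geojson(path)
  validate_points(pts)
  pts
}

read_points_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  nm <- names(df)
  xcol <- intersect(c("x_px", "x"), nm)[1]
  ycol <- intersect(c("y_px", "y"), nm)[1]
  if (is.na(xcol) || is.na(ycol)) {
    abort("CSV must contain x_px,y_px (or x,y) columns", class = "mitoquant_format_error")
  }
  x <- suppressWarnings(as.numeric(df[[xcol]]))
  y <- suppressWarnings(as.numeric(df[[ycol]]))
  bad <- which(is.na(x) & !is.na(df[[xcol]]) | is.na(y) & !is.na(df[[ycol]]))
  if (length(bad) > 0) {
    abort(paste0("non-numeric coordinate at row ", bad[1]), class = "mitoquant_parse_error")
  }
  tibble::tibble(
    x = x,
    y = y,
    annotator = if ("annotator" %in% nm) as.character(df$annotator) else NA_character_,
    label = if ("label" %in% nm) as.character(df$label) else NA_character_
  )
}

read_points_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% list()
  rows <- purrr::map(feats, function(f) {
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Point")) {
      return(NULL)
    }
    cc <- unlist(geom$coordinates)
    if (length(cc) < 2 || !is.numeric(cc)) {
      abort("Point feature with malformed coordinates", class = "mitoquant_parse_error")
    }
    props <- f$properties %||% list()
    tibble::tibble(
      x = cc[1], y = cc[2],
      annotator = as.character(props$annotator %||% NA_character_),
      label = as.character(props$classification$name %||% props$label %||% NA_character_)
    )
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) {
    return(tibble::tibble(x = double(), y = double(),
                          annotator = character(), label = character()))
  }
  dplyr::bind_rows(rows)
}

validate_points <- function(pts) {
  if (any(!is.finite(pts$x)) || any(!is.finite(pts$y))) {
    abort("point coordinates must be finite", class = "mitoquant_parse_error")
  }
  if (any(pts$x < 0) || any(pts$y < 0)) {
    abort("point coordinates must be non-negative pixels", class = "mitoquant_parse_error")
  }
  invisible(pts)
}

#' Write point annotations
#'
#' Writes a point tibble in one of the dialects [read_points()] reads, so that
#' a write/read cycle is the identity on coordinates, annotator ids and labels.
#'
#' @param points Tibble with columns `x`, `y` and optionally `annotator`, `label`.
#' @param path Output path.
#' @param format `"auto"`, `"csv"` or `"geojson"`.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path, format = c("auto", "csv", "geojson")) {
  format <- match.arg(format)
  points <- as_point_tibble(points)
  if (format == "auto") {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) "geojson" else "csv"
  }
  if (format == "csv") {
    out <- tibble::tibble(x_px = points$x, y_px = points$y,
                          annotator = points$annotator, label = points$label)
    readr::write_csv(out, path, progress = FALSE)
  } else {
    feats <- purrr::pmap(points, function(x, y, annotator, label, ...) {
      props <- list()
      if (!is.na(annotator)) props$annotator <- annotator
      if (!is.na(label)) props$classification <- list(name = label)
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = c(x, y)),
           properties = props)
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# Coerce any data frame with x/y columns into the canonical point tibble.
as_point_tibble <- function(points) {
  if (!is.data.frame(points)) {
    abort("points must be a data frame with x and y columns",
          class = "mitoquant_format_error")
  }
  nm <- names(points)
  xcol <- intersect(c("x", "x_px"), nm)[1]
  ycol <- intersect(c("y", "y_px"), nm)[1]
  if (is.na(xcol) || is.na(ycol)) {
    abort("points must have x and y (or x_px/y_px) columns",
          class = "mitoquant_format_error")
  }
  tibble::tibble(
    x = as.numeric(points[[xcol]]),
    y = as.numeric(points[[ycol]]),
    annotator = if ("annotator" %in% nm) as.character(points$annotator) else NA_character_,
    label = if ("label" %in% nm) as.character(points$label) else NA_character_
  )
}

#' Construct a region mask from labeled polygons
#'
#' A region mask marks slide area to exclude from mitotic-count calculation:
#' background, out-of-focus area, or non-tumor tissue marked by a pathologist.
#' Grid cells overlapping excluded area beyond a tolerated fraction are removed
#' from every hotspot quantity (see [compute_eligibility()]).
#'
#' @param polygons List of polygons; each either a 2-column matrix/data frame of
#'   vertex coordinates (pixels) or a list with elements `xy` and `label`.
#' @param labels Character vector of labels, recycled; one of `"background"`,
#'   `"out_of_focus"`, `"non_tumor"`. Unlabeled polygons default to
#'   `"non_tumor"` (conservative: excluded).
#' @return An object of class `region_mask`.
#' @export
mask_polygons <- function(polygons = list(), labels = "non_tumor") {
  if (length(polygons) > 0) {
    labels <- rep_len(labels, length(polygons))
  } else {
    labels <- character()
  }
  polys <- purrr::map2(polygons, labels, function(p, lab) {
    if (is.list(p) && !is.null(p$xy)) {
      lab <- p$label %||% lab
      p <- p$xy
    }
    xy <- as.matrix(as.data.frame(p))
    storage.mode(xy) <- "double"
    if (ncol(xy) != 2 || nrow(xy) < 3) {
      abort("each polygon needs >= 3 vertices with 2 coordinates",
            class = "mitoquant_geometry_error")
    }
    # drop an explicitly closed last vertex
    if (all(xy[1, ] == xy[nrow(xy), ]) && nrow(xy) > 3) xy <- xy[-nrow(xy), , drop = FALSE]
    list(xy = xy, label = lab)
  })
  structure(list(type = "polygons", polygons = polys, raster = NULL, scale_px = 1),
            class = "region_mask")
}

#' Construct a region mask from a binary raster
#'
#' @param raster Numeric or logical matrix; values `> 0` mark excluded area.
#'   Rows index y, columns index x (image convention).
#' @param scale_px Edge length of one raster pixel in WSI pixels (default 1).
#' @return An object of class `region_mask`.
#' @export
mask_raster <- function(raster, scale_px = 1) {
  raster <- as.matrix(raster)
  if (scale_px <= 0) abort("scale_px must be positive", class = "mitoquant_parameter_error")
  structure(list(type = "raster", polygons = list(),
                 raster = raster > 0, scale_px = scale_px),
            class = "region_mask")
}

#' An empty region mask (nothing excluded)
#' @return An object of class `region_mask` with no regions.
#' @export
empty_mask <- function() mask_polygons(list())

#' @export
print.region_mask <- function(x, ...) {
  if (x$type == "polygons") {
    cat("<region_mask> ", length(x$polygons), " polygon(s)\n", sep = "")
  } else {
    cat("<region_mask> raster ", nrow(x$raster), "x", ncol(x$raster),
        " (scale ", x$scale_px, " px)\n", sep = "")
  }
  invisible(x)
}

#' Read an exclusion/tumor mask
#'
#' GeoJSON masks are `FeatureCollection`s of `Polygon` features (first ring
#' used; holes are not supported) with the label in
#' `properties$classification$name` or `properties$label`; unlabeled polygons
#' default to `non_tumor`. Raster masks are PNG or TIFF images whose nonzero
#' pixels mark excluded area.
#'
#' Self-intersecting polygons are rejected with an error naming the feature.
#'
#' @param path Path to the mask file.
#' @param format `"auto"`, `"geojson"` or `"raster"`.
#' @param scale_px For raster masks, WSI pixels per raster pixel.
#' @return An object of class `region_mask`.
#' @export
read_mask <- function(path, format = c("auto", "geojson", "raster"), scale_px = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("mask file not found: ", path), class = "mitoquant_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.(png|tif|tiff)$", path, ignore.case = TRUE)) "raster" else "geojson"
  }
  if (format == "raster") {
    img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
      png::readPNG(path)
    } else {
      tiff::readTIFF(path)
    }
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(mask_raster(img > 0, scale_px = scale_px))
  }
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% list()
  polys <- list()
  labels <- character()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) next
    ring <- geom$coordinates[[1]]
    xy <- do.call(rbind, purrr::map(ring, ~ as.numeric(unlist(.x))[1:2]))
    if (all(xy[1, ] == xy[nrow(xy), ]) && nrow(xy) > 3) xy <- xy[-nrow(xy), , drop = FALSE]
    if (!polygon_is_simple(xy)) {
      abort(paste0("self-intersecting polygon in feature ", i),
            class = "mitoquant_geometry_error")
    }
    props <- f$properties %||% list()
    polys[[length(polys) + 1]] <- xy
    labels <- c(labels,
                as.character(props$classification$name %||% props$label %||% "non_tumor"))
  }
  mask_polygons(polys, labels)
}

#' Write an analysis report
#'
#' Mitotic-count reports ([quantify_all()] results) are written as JSON; plain
#' data frames (metric tables) as tab-separated text. Both round-trip through
#' [read_report()] with equal values.
#'
#' @param report An `mc_report` object or a data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "mc_report")) {
    jsonlite::write_json(as_report_list(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else if (is.data.frame(report)) {
    readr::write_tsv(report, path, progress = FALSE)
  } else {
    abort("report must be an mc_report or a data frame",
          class = "mitoquant_format_error")
  }
  invisible(path)
}

#' Re-read a report written by [write_report()]
#'
#' @param path Path written by [write_report()].
#' @return For JSON reports, a named list of values; for tables, a tibble.
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Run configuration
#'
#' Bundles the geometric and algorithmic parameters shared across the analysis.
#' Defaults reproduce the standard HPF geometry: a 1600 px square field at
#' 0.25 um/px is 400 um x 400 um = 0.16 mm^2, and the 15 um matching radius is
#' 60 px.
#'
#' @param hpf_edge_px HPF edge length in pixels (> 0).
#' @param microns_per_px Scanner resolution in micrometres per pixel (> 0).
#' @param path_length Number of connected HPFs in the hotspot path (>= 1).
#' @param match_radius_um Matching radius for point evaluation, micrometres (> 0).
#' @param eligibility_min_fraction Minimum unexcluded area fraction for a grid
#'   cell to be eligible, in `[0, 1]`.
#' @param random_reps Draws for the random-field quantifier.
#' @param bootstrap_reps Resamples for bootstrap confidence intervals.
#' @param seed Integer seed for stochastic components, or `NULL`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(hpf_edge_px = 1600, microns_per_px = 0.25,
                       path_length = 10, match_radius_um = 15,
                       eligibility_min_fraction = 0.99,
                       random_reps = 1000, bootstrap_reps = 10000, seed = NULL) {
  if (hpf_edge_px <= 0 || microns_per_px <= 0 || match_radius_um <= 0 ||
      path_length < 1) {
    abort("invalid run configuration", class = "mitoquant_parameter_error")
  }
  if (eligibility_min_fraction < 0 || eligibility_min_fraction > 1) {
    abort("eligibility_min_fraction must be in [0, 1]",
          class = "mitoquant_parameter_error")
  }
  structure(list(hpf_edge_px = hpf_edge_px, microns_per_px = microns_per_px,
                 path_length = path_length, match_radius_um = match_radius_um,
                 eligibility_min_fraction = eligibility_min_fraction,
                 random_reps = random_reps, bootstrap_reps = bootstrap_reps,
                 seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [run_config()] defaults.
#'
#' @param path YAML file with any subset of the [run_config()] fields.
#' @return A `run_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    abort(paste0("unknown configuration keys: ", paste(extra, collapse = ", ")),
          class = "mitoquant_parameter_error")
  }
  do.call(run_config, vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
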