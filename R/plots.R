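#' Plot an HPF grid as a count heatmap
#'
#' Eligible cells are shaded by mitosis count; ineligible cells are hatched
#' out in grey. An optional path or window result is drawn on top, which is
#' the usual way to inspect where the hotspot search landed.
#'
#' @param object An [hpf_grid()].
#' @param highlight Optional `path_result` or `window_result` to overlay.
#' @param ... Unused.
#' @return A ggplot object. Axes are cell indices; y is flipped so the plot
#'   matches image orientation (y down).
#' @method autoplot hpf_grid
#' @export
autoplot.hpf_grid <- function(object, highlight = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(data = df[df$eligible, ],
                       ggplot2::aes(fill = .data$count), color = "grey80") +
    ggplot2::geom_tile(data = df[!df$eligible, ],
                       fill = "grey50", color = "grey80", alpha = 0.6) +
    ggplot2::scale_fill_viridis_c(name = "mitoses") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "HPF column", y = "HPF row") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    if (inherits(highlight, "path_result") && highlight$found) {
      p <- p +
        ggplot2::geom_path(data = highlight$cells, color = "red", linewidth = 1) +
        ggplot2::geom_point(data = highlight$cells, color = "red", size = 2)
    } else if (inherits(highlight, "window_result") && highlight$found) {
      h <- highlight$shape[1]
      w <- highlight$shape[2]
      rect <- tibble::tibble(xmin = highlight$anchor[2] - 0.5,
                             xmax = highlight$anchor[2] + w - 0.5,
                             ymin = highlight$anchor[1] - 0.5,
                             ymax = highlight$anchor[1] + h - 0.5)
      p <- p + ggplot2::geom_rect(
        data = rect, inherit.aes = FALSE, color = "red", fill = NA,
        linewidth = 1,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = .data$ymin, ymax = .data$ymax))
    }
  }
  p
}

#' Plot a six-method MC report
#'
#' Bar chart of the hotspot MC under each quantifier, with the random-field
#' distribution shown as its mean and 95% interval. The expected ordering —
#' top-10 unconnected above the DFS path above the fixed windows above the
#' slide average — is immediately visible.
#'
#' @param object An `mc_report` from [quantify_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mc_report
#' @export
autoplot.mc_report <- function(object, ...) {
  df <- tidy(object)
  df$method <- factor(df$method, levels = rev(df$method))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$mc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "MC per 10 HPFs") +
    ggplot2::theme_minimal()
  if (!is.null(object$random)) {
    err <- tibble::tibble(method = "random_mean",
                          lo = object$random$ci95[1], hi = object$random$ci95[2])
    p <- p + ggplot2::geom_errorbar(
      data = err, width = 0.3, color = "magenta",
      ggplot2::aes(x = .data$method, ymin = .data$lo, ymax = .data$hi),
      inherit.aes = FALSE)
  }
  p
}

#' Plot a group-size experiment
#'
#' Precision and sensitivity of majority-vote consensus against group size,
#' as per-size means with +/- 1 SD ribbons over replicates.
#'
#' @param object A `group_experiment` from [group_sampling_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_experiment
#' @export
autoplot.group_experiment <- function(object, ...) {
  s <- glance(object)
  long <- dplyr::bind_rows(
    tibble::tibble(group_size = s$group_size, metric = "precision",
                   mean = s$precision_mean, sd = s$precision_sd),
    tibble::tibble(group_size = s$group_size, metric = "sensitivity",
                   mean = s$sensitivity_mean, sd = s$sensitivity_sd)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group_size, y = .data$mean,
                                     color = .data$metric, fill = .data$metric)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "group size (readers)", y = "metric") +
    ggplot2::theme_minimal()
}

#' Export hotspot cells as a GeoJSON overlay
#'
#' Writes the cell boundaries of a winning path or window as GeoJSON polygons
#' in slide pixel coordinates, for loading into a slide viewer on top of the
#' WSI.
#'
#' @param grid The [hpf_grid()] the result was computed on.
#' @param result A `path_result` or `window_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_overlay_geojson <- function(grid, result, path) {
  edge <- grid$spec$hpf_edge_px
  dx <- grid$spec$origin_offset[1]
  dy <- grid$spec$origin_offset[2]
  cells <- if (inherits(result, "path_result")) {
    result$cells
  } else if (inherits(result, "window_result")) {
    h <- result$shape[1]
    w <- result$shape[2]
    tidyr::expand_grid(row = result$anchor[1] + seq_len(h) - 1L,
                       col = result$anchor[2] + seq_len(w) - 1L)
  } else {
    abort("result must be a path_result or window_result",
          class = "mitoquant_format_error")
  }
  feats <- purrr::pmap(cells, function(row, col, ...) {
    x0 <- dx + col * edge
    y0 <- dy + row * edge
    ring <- list(c(x0, y0), c(x0 + edge, y0), c(x0 + edge, y0 + edge),
                 c(x0, y0 + edge), c(x0, y0))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(row = row, col = col,
                           classification = list(name = "hotspot_hpf")))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
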