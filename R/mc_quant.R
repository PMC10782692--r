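#' Exact maximum mitotic count over a connected path of HPFs
#'
#' Finds the simple path of `L` edge-adjacent, pairwise-distinct, eligible
#' grid cells with the largest total mitosis count, by recursive depth-first
#' search with backtracking. The search is exhaustive over all simple
#' `L`-paths; pruning is admissible branch-and-bound only, so the returned
#' count is the mathematical maximum, not a heuristic. Two HPFs are connected
#' iff they share an edge (4-neighborhood); diagonal contact does not count.
#'
#' Among equally optimal paths the first one found under the deterministic
#' search order is returned, and the path is canonicalized so that a path and
#' its reverse are the same solution.
#'
#' @param grid An [hpf_grid()].
#' @param L Path length in cells (default 10, the WHO "10 consecutive HPFs").
#' @return An object of class `path_result`: `found` (logical), `count`
#'   (total mitoses), `cells` (tibble of `row`, `col` in path order, absolute
#'   cell indices). When no valid `L`-path exists, `found` is `FALSE` and
#'   `count` is `NA` — distinguishable from a genuine count of 0.
#' @seealso [brute_force_max_path()] for the enumeration oracle,
#'   [quantify_all()] for the full six-method report.
#' @export
#' @examples
#' g <- hpf_grid(matrix(c(3, 0, 1, 2, 9, 1, 0, 4, 1), 3, byrow = TRUE))
#' dfs_max_path(g, L = 3)   # 4 + 9 + 2 = 15
dfs_max_path <- function(grid, L = 10) {
  stopifnot(inherits(grid, "hpf_grid"))
  if (L < 1) abort("L must be >= 1", class = "mitoquant_parameter_error")
  res <- .dfs_max_path_cpp(grid$counts, grid$eligible, as.integer(L))
  if (!res$found) {
    return(new_path_result(found = FALSE, grid = grid))
  }
  new_path_result(found = TRUE, count = res$count, path = res$path, grid = grid)
}

new_path_result <- function(found, count = NA_real_, path = NULL, grid = NULL) {
  if (found) {
    # canonical orientation: smaller row-major endpoint first
    nc <- ncol(grid$counts)
    key <- function(rc) (rc[1] - 1) * nc + rc[2]
    if (key(path[nrow(path), ]) < key(path[1, ])) path <- path[rev(seq_len(nrow(path))), ]
    cells <- tibble::tibble(row = path[, 1] + grid$row0 - 1L,
                            col = path[, 2] + grid$col0 - 1L)
  } else {
    cells <- tibble::tibble(row = integer(), col = integer())
  }
  structure(list(found = found, count = if (found) count else NA_real_,
                 cells = cells),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  if (!x$found) {
    cat("<path_result> no valid path\n")
  } else {
    cat("<path_result> MC =", x$count, "over", nrow(x$cells), "cells:",
        paste0("(", x$cells$row, ",", x$cells$col, ")", collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Brute-force maximum-path oracle
#'
#' Enumerates every simple path of `L` edge-adjacent eligible cells (a path
#' and its reverse counted once) and returns the maximum total count. Serves
#' as an independent check on [dfs_max_path()]; refuses grids larger than 36
#' cells, where exhaustive enumeration stops being practical.
#'
#' @inheritParams dfs_max_path
#' @return A `path_result`, as for [dfs_max_path()].
#' @export
brute_force_max_path <- function(grid, L = 10) {
  stopifnot(inherits(grid, "hpf_grid"))
  if (L < 1) abort("L must be >= 1", class = "mitoquant_parameter_error")
  nr <- nrow(grid$counts)
  nc <- ncol(grid$counts)
  if (nr * nc > 36) {
    abort("brute-force enumeration is limited to grids of <= 36 cells",
          class = "mitoquant_size_error")
  }
  cnt <- grid$counts
  elig <- grid$eligible
  best <- -Inf
  best_path <- NULL
  visited <- matrix(FALSE, nr, nc)
  path <- matrix(0L, L, 2)
  recurse <- function(r, c, depth, total) {
    path[depth, ] <<- c(r, c)
    if (depth == L) {
      # dedupe reverse: keep only paths whose start <= end in row-major order
      s <- (path[1, 1] - 1) * nc + path[1, 2]
      e <- (path[L, 1] - 1) * nc + path[L, 2]
      if (s <= e && total > best) {
        best <<- total
        best_path <<- path
      }
      return(invisible())
    }
    for (k in seq_len(4)) {
      r2 <- r + c(-1L, 0L, 1L, 0L)[k]
      c2 <- c + c(0L, 1L, 0L, -1L)[k]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!elig[r2, c2] || visited[r2, c2]) next
      visited[r2, c2] <<- TRUE
      recurse(r2, c2, depth + 1L, total + cnt[r2, c2])
      visited[r2, c2] <<- FALSE
    }
    invisible()
  }
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!elig[r, c]) next
      visited[r, c] <- TRUE
      recurse(r, c, 1L, cnt[r, c])
      visited[r, c] <- FALSE
    }
  }
  if (!is.finite(best)) {
    return(new_path_result(found = FALSE, grid = grid))
  }
  new_path_result(found = TRUE, count = best, path = best_path, grid = grid)
}

#' Maximum mitotic count in a fixed rectangular window
#'
#' Scans every placement of an `h x w` window whose cells are all eligible and
#' returns the one with the largest total count. Windows touching an
#' ineligible cell are skipped, mirroring the path search's eligibility rule.
#' Ties break to the first placement in row-major anchor order.
#'
#' @param grid An [hpf_grid()].
#' @param shape Integer `(h, w)`: window height and width in cells. The linear
#'   arrangements are `(10, 1)` and `(1, 10)`; the rectangular ones `(5, 2)`
#'   and `(2, 5)`.
#' @return An object of class `window_result`: `found`, `count`, `anchor`
#'   (absolute `(row, col)` of the top-left cell), `shape`. `found = FALSE`
#'   when no placement fits.
#' @export
max_window <- function(grid, shape) {
  stopifnot(inherits(grid, "hpf_grid"), length(shape) == 2)
  h <- as.integer(shape[1])
  w <- as.integer(shape[2])
  if (h < 1 || w < 1) abort("window shape must be positive", class = "mitoquant_parameter_error")
  nr <- nrow(grid$counts)
  nc <- ncol(grid$counts)
  best <- -Inf
  anchor <- NULL
  if (nr >= h && nc >= w) {
    for (i in seq_len(nr - h + 1)) {
      for (j in seq_len(nc - w + 1)) {
        sub_e <- grid$eligible[i:(i + h - 1), j:(j + w - 1)]
        if (!all(sub_e)) next
        s <- sum(grid$counts[i:(i + h - 1), j:(j + w - 1)])
        if (s > best) {
          best <- s
          anchor <- c(i, j)
        }
      }
    }
  }
  if (!is.finite(best)) {
    return(structure(list(found = FALSE, count = NA_real_, anchor = NULL,
                          shape = c(h, w)),
                     class = "window_result"))
  }
  structure(list(found = TRUE, count = best,
                 anchor = c(anchor[1] + grid$row0 - 1L, anchor[2] + grid$col0 - 1L),
                 shape = c(h, w)),
            class = "window_result")
}

#' @export
print.window_result <- function(x, ...) {
  if (!x$found) {
    cat("<window_result> no ", x$shape[1], "x", x$shape[2], " placement fits\n", sep = "")
  } else {
    cat("<window_result> MC = ", x$count, " in ", x$shape[1], "x", x$shape[2],
        " window at (", x$anchor[1], ",", x$anchor[2], ")\n", sep = "")
  }
  invisible(x)
}

#' Average mitotic count per 10 HPFs
#'
#' Total mitoses in eligible (tumor) cells divided by the number of eligible
#' cells, times 10: the slide-wide mitotic density expressed on the reporting
#' scale of 10 HPFs.
#'
#' @param grid An [hpf_grid()].
#' @return A single number.
#' @export
average_mc_per_10 <- function(grid) {
  stopifnot(inherits(grid, "hpf_grid"))
  n_elig <- sum(grid$eligible)
  if (n_elig == 0) {
    abort("no eligible cells: average MC per 10 HPFs is undefined",
          class = "mitoquant_value_error")
  }
  sum(grid$counts[grid$eligible]) / n_elig * 10
}

#' Mitotic count in randomly sampled HPFs
#'
#' Draws `n_fields` distinct eligible cells uniformly at random, `reps` times,
#' and summarises the distribution of the per-draw total counts. This is the
#' "random 10 HPFs" quantifier: it shows what a reader sampling fields blindly
#' would see, in contrast to hotspot-seeking methods.
#'
#' @param grid An [hpf_grid()].
#' @param n_fields Cells per draw (default 10).
#' @param reps Number of draws (default 1000).
#' @param seed Optional integer seed; the summary is reproducible under it.
#' @return An object of class `mc_distribution`: `mean`, `sd`, `median`,
#'   `percentiles` (2.5/25/50/75/97.5), `ci95`, `reps`, `n_fields`, `seed`,
#'   and the raw `draws`.
#' @export
random_mc_distribution <- function(grid, n_fields = 10, reps = 1000, seed = NULL) {
  stopifnot(inherits(grid, "hpf_grid"))
  vals <- grid$counts[grid$eligible]
  if (length(vals) < n_fields) {
    abort("fewer eligible cells than n_fields", class = "mitoquant_sampling_error")
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(seq_len(reps),
                  function(i) sum(sample(vals, n_fields, replace = FALSE)),
                  numeric(1))
  qs <- quantile(draws, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  structure(list(mean = mean(draws), sd = sd(draws), median = qs[3],
                 percentiles = stats::setNames(qs, c("p2.5", "p25", "p50", "p75", "p97.5")),
                 ci95 = c(qs[1], qs[5]), reps = reps, n_fields = n_fields,
                 seed = seed, draws = draws),
            class = "mc_distribution")
}

#' @export
print.mc_distribution <- function(x, ...) {
  cat("<mc_distribution> mean ", round(x$mean, 2), ", SD ", round(x$sd, 2),
      ", CI95 [", x$ci95[1], ", ", x$ci95[2], "] over ", x$reps, " draws of ",
      x$n_fields, " fields\n", sep = "")
  invisible(x)
}

#' Sum of the top-k unconnected HPFs
#'
#' Ranks eligible cells by count and sums the `k` largest. With `k = 10` this
#' is the maximum possible MC observable in any 10 HPFs of the slide,
#' connected or not — an upper bound on every other quantifier.
#'
#' @param grid An [hpf_grid()].
#' @param k Number of fields (default 10).
#' @return A single number.
#' @export
top_k_unconnected <- function(grid, k = 10) {
  stopifnot(inherits(grid, "hpf_grid"))
  vals <- grid$counts[grid$eligible]
  if (length(vals) < k) {
    abort("fewer eligible cells than k", class = "mitoquant_sampling_error")
  }
  sum(sort(vals, decreasing = TRUE)[seq_len(k)])
}

#' Grade contribution of the mitotic count alone
#'
#' Maps an MC per 10 HPFs to the grade supported by the mitotic-count
#' criterion in isolation: grade 2 at `mc >= 4`, grade 3 at `mc >= 20` under
#' the defaults. This is explicitly *not* a full WHO grade — other
#' histological and molecular criteria are outside this package's scope — and
#' results should always be labeled "MC criterion only".
#'
#' @param mc Mitotic count(s) per 10 HPFs; vectorized.
#' @param thresholds Length-2 numeric `(t2, t3)`, `t2 < t3`.
#' @return Integer vector in `{1, 2, 3}`.
#' @export
#' @examples
#' grade_from_mc(c(0, 4, 19, 21))   # 1 2 2 3
grade_from_mc <- function(mc, thresholds = c(4, 20)) {
  if (any(mc < 0)) abort("mc must be non-negative", class = "mitoquant_parameter_error")
  if (length(thresholds) != 2 || thresholds[1] >= thresholds[2]) {
    abort("thresholds must be (t2, t3) with t2 < t3", class = "mitoquant_parameter_error")
  }
  as.integer(1 + (mc >= thresholds[1]) + (mc >= thresholds[2]))
}

#' Quantify the hotspot mitotic count by all six methods
#'
#' Runs the DFS path maximum, the linear (10x1, 1x10) and rectangular (5x2,
#' 2x5) window maxima, the slide-wide average per 10 HPFs, the random-field
#' distribution, and the top-10-unconnected sum on one slide's annotations,
#' and attaches the MC-criterion-only grade of the DFS count.
#'
#' @param points Data frame of mitosis points (`x`, `y` in pixels).
#' @param spec A [grid_spec()].
#' @param mask Optional `region_mask` of excluded area.
#' @param config A [run_config()]; supplies path length, eligibility
#'   threshold, random-draw count and seed.
#' @return An object of class `mc_report` with fields `dfs`, `linear_v`,
#'   `linear_h`, `rect_v`, `rect_h`, `average_per_10`, `random`,
#'   `top10_unconnected`, `grade_mc_only`, plus the `grid` and `config`.
#'   Use [tidy()] for a long method/value table and [glance()] for a one-row
#'   summary.
#' @export
quantify_all <- function(points, spec = grid_spec(), mask = NULL,
                         config = run_config()) {
  grid <- make_grid(points, spec, mask, config$eligibility_min_fraction)
  L <- config$path_length
  if (grid$n_points == 0) {
    # a slide without a single mitosis has MC 0 under every quantifier,
    # whatever the (degenerate) grid extent
    zero_win <- function(shape) structure(
      list(found = TRUE, count = 0, anchor = c(grid$row0, grid$col0), shape = shape),
      class = "window_result")
    zero_path <- structure(list(found = TRUE, count = 0,
                                cells = tibble::tibble(row = integer(), col = integer())),
                           class = "path_result")
    return(structure(list(
      dfs = zero_path, linear_v = zero_win(c(L, 1)), linear_h = zero_win(c(1, L)),
      rect_v = zero_win(c(max(1, L %/% 2), min(L, 2))),
      rect_h = zero_win(c(min(L, 2), max(1, L %/% 2))),
      average_per_10 = 0,
      random = NULL, top10_unconnected = 0, grade_mc_only = grade_from_mc(0),
      grid = grid, config = config), class = "mc_report"))
  }
  dfs <- dfs_max_path(grid, L)
  lin_v <- max_window(grid, c(L, 1))
  lin_h <- max_window(grid, c(1, L))
  rect_v <- max_window(grid, c(max(1, L %/% 2), min(L, 2)))
  rect_h <- max_window(grid, c(min(L, 2), max(1, L %/% 2)))
  n_elig <- sum(grid$eligible)
  avg <- if (n_elig > 0) average_mc_per_10(grid) else NA_real_
  rnd <- if (n_elig >= L) {
    random_mc_distribution(grid, L, config$random_reps, config$seed)
  }
  topk <- if (n_elig >= L) top_k_unconnected(grid, L) else NA_real_
  grade <- if (dfs$found) grade_from_mc(dfs$count) else NA_integer_
  structure(list(dfs = dfs, linear_v = lin_v, linear_h = lin_h,
                 rect_v = rect_v, rect_h = rect_h, average_per_10 = avg,
                 random = rnd, top10_unconnected = topk,
                 grade_mc_only = grade, grid = grid, config = config),
            class = "mc_report")
}

#' @export
print.mc_report <- function(x, ...) {
  cat("<mc_report> hotspot MC per ", x$config$path_length, " HPFs\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @rdname quantify_all
#' @param x An `mc_report`.
#' @param ... Unused.
#' @method tidy mc_report
#' @export
tidy.mc_report <- function(x, ...) {
  tibble::tibble(
    method = c("dfs", "linear_v", "linear_h", "rect_v", "rect_h",
               "average_per_10", "random_mean", "top10_unconnected"),
    mc = c(x$dfs$count,
           x$linear_v$count, x$linear_h$count,
           x$rect_v$count, x$rect_h$count,
           x$average_per_10,
           if (is.null(x$random)) NA_real_ else x$random$mean,
           x$top10_unconnected)
  )
}

#' @rdname quantify_all
#' @method glance mc_report
#' @export
glance.mc_report <- function(x, ...) {
  max_or_na <- function(...) {
    v <- c(...)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }
  tibble::tibble(
    dfs_mc = x$dfs$count,
    linear_max = max_or_na(x$linear_v$count, x$linear_h$count),
    rect_max = max_or_na(x$rect_v$count, x$rect_h$count),
    average_per_10 = x$average_per_10,
    random_mean = if (is.null(x$random)) NA_real_ else x$random$mean,
    top10_unconnected = x$top10_unconnected,
    grade_mc_only = x$grade_mc_only,
    n_points = x$grid$n_points,
    n_eligible_cells = sum(x$grid$eligible)
  )
}

# serializable view of an mc_report (for write_report)
as_report_list <- function(x) {
  list(
    dfs = list(found = x$dfs$found, count = x$dfs$count,
               cells = as.data.frame(x$dfs$cells)),
    linear_v = x$linear_v$count, linear_h = x$linear_h$count,
    rect_v = x$rect_v$count, rect_h = x$rect_h$count,
    average_per_10 = x$average_per_10,
    random = if (!is.null(x$random)) {
      list(mean = x$random$mean, sd = x$random$sd,
           percentiles = as.list(x$random$percentiles),
           ci95 = x$random$ci95, reps = x$random$reps,
           n_fields = x$random$n_fields, seed = x$random$seed)
    },
    top10_unconnected = x$top10_unconnected,
    grade_mc_only = x$grade_mc_only,
    config = unclass(x$config)
  )
}

#' Sensitivity of the quantifiers to the grid anchor
#'
#' The HPF tiling has an arbitrary anchor: shifting the grid origin within one
#' cell edge changes how points fall into cells and hence every per-cell
#' quantity. This scan recomputes the requested quantifiers at each offset and
#' reports the per-method maximum over the scan.
#'
#' @param points Data frame of mitosis points.
#' @param spec A [grid_spec()]; its own offset is replaced by each scan offset.
#' @param mask Optional `region_mask`.
#' @param offsets Data frame or matrix with columns/cols `dx`, `dy` (pixels,
#'   each in `[0, hpf_edge_px)`), or a list of length-2 vectors.
#' @param methods Subset of `c("dfs", "linear", "rect", "average", "topk")`.
#' @param config A [run_config()].
#' @return A tibble with one row per offset and one column per method value;
#'   the attribute `scan_max` holds the per-method maximum over all offsets.
#' @export
origin_shift_scan <- function(points, spec = grid_spec(), mask = NULL,
                              offsets = NULL,
                              methods = c("dfs", "linear", "rect", "average", "topk"),
                              config = run_config()) {
  if (is.list(offsets) && !is.data.frame(offsets)) {
    offsets <- do.call(rbind, offsets)
  }
  offsets <- as.data.frame(offsets)
  if (is.null(offsets) || nrow(offsets) == 0) {
    abort("offsets must be a non-empty list of (dx, dy)",
          class = "mitoquant_parameter_error")
  }
  names(offsets)[1:2] <- c("dx", "dy")
  methods <- match.arg(methods, several.ok = TRUE)
  L <- config$path_length
  rows <- purrr::pmap(offsets, function(dx, dy, ...) {
    sp <- shift_origin(spec, dx, dy)
    grid <- make_grid(points, sp, mask, config$eligibility_min_fraction)
    out <- tibble::tibble(dx = dx, dy = dy)
    if ("dfs" %in% methods) out$dfs <- dfs_max_path(grid, L)$count
    if ("linear" %in% methods) {
      out$linear_v <- max_window(grid, c(L, 1))$count
      out$linear_h <- max_window(grid, c(1, L))$count
    }
    if ("rect" %in% methods) {
      out$rect_v <- max_window(grid, c(max(1, L %/% 2), min(L, 2)))$count
      out$rect_h <- max_window(grid, c(min(L, 2), max(1, L %/% 2)))$count
    }
    if ("average" %in% methods) {
      out$average_per_10 <- if (sum(grid$eligible) > 0) average_mc_per_10(grid) else NA_real_
    }
    if ("topk" %in% methods) {
      out$top10_unconnected <- if (sum(grid$eligible) >= L) top_k_unconnected(grid, L) else NA_real_
    }
    out
  })
  tab <- dplyr::bind_rows(rows)
  value_cols <- setdiff(names(tab), c("dx", "dy"))
  attr(tab, "scan_max") <- vapply(tab[value_cols],
                                  function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE),
                                  numeric(1))
  tab
}

# Structural validity check used by tests and by cautious callers: a
# path_result must visit distinct, pairwise edge-adjacent, eligible cells
# whose counts sum to its count.
validate_path_result <- function(res, grid, L) {
  if (!res$found) return(invisible(TRUE))
  cells <- res$cells
  stopifnot(nrow(cells) == L)
  ij <- cbind(cells$row - grid$row0 + 1L, cells$col - grid$col0 + 1L)
  if (anyDuplicated(paste(ij[, 1], ij[, 2]))) {
    abort("path visits a cell twice", class = "mitoquant_invariant_error")
  }
  if (L > 1) {
    dr <- abs(diff(ij[, 1]))
    dc <- abs(diff(ij[, 2]))
    if (!all(dr + dc == 1)) {
      abort("consecutive path cells are not edge-adjacent",
            class = "mitoquant_invariant_error")
    }
  }
  if (!all(grid$eligible[ij])) {
    abort("path visits an ineligible cell", class = "mitoquant_invariant_error")
  }
  if (sum(grid$counts[ij]) != res$count) {
    abort("path count does not equal the sum over its cells",
          class = "mitoquant_invariant_error")
  }
  invisible(TRUE)
}
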