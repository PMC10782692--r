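#' Radius-based one-to-one matching of detections against ground truth
#'
#' A prediction and a truth point may match when their Euclidean distance is
#' at most `radius_um` (inclusive, so an annotation exactly on the boundary
#' still counts; under the defaults 15 um = 60 px). Matching is one-to-one and
#' greedy by ascending distance, with deterministic ties broken by (truth
#' index, prediction index): each truth point absorbs at most one prediction,
#' so two marks on the same mitosis yield one TP and one FP rather than two
#' TPs. Unmatched predictions are false positives; unmatched truth points are
#' false negatives.
#'
#' @param pred Data frame of predicted points (`x`, `y` in pixels).
#' @param truth Data frame of ground-truth points.
#' @param radius_um Matching radius in micrometres (> 0).
#' @param mpp Micrometres per pixel.
#' @return An object of class `match_result`: counts `tp`, `fp`, `fn` and a
#'   tibble `pairs` (`pred_idx`, `truth_idx`, `distance_um`). Conservation
#'   holds by construction: `tp + fp == nrow(pred)`, `tp + fn == nrow(truth)`.
#' @export
match_detections <- function(pred, truth, radius_um = 15, mpp = 0.25) {
  if (radius_um <= 0 || mpp <= 0) {
    abort("radius_um and mpp must be positive", class = "mitoquant_parameter_error")
  }
  pred <- as_point_tibble(pred)
  truth <- as_point_tibble(truth)
  np <- nrow(pred)
  nt <- nrow(truth)
  radius_px <- radius_um / mpp
  pairs <- tibble::tibble(pred_idx = integer(), truth_idx = integer(),
                          distance_um = double())
  if (np > 0 && nt > 0) {
    d <- sqrt(outer(pred$x, truth$x, "-")^2 + outer(pred$y, truth$y, "-")^2)
    cand <- which(d <= radius_px, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(d[cand], cand[, 2], cand[, 1])
      cand <- cand[ord, , drop = FALSE]
      used_p <- logical(np)
      used_t <- logical(nt)
      keep_p <- integer()
      keep_t <- integer()
      keep_d <- double()
      for (i in seq_len(nrow(cand))) {
        pi <- cand[i, 1]
        ti <- cand[i, 2]
        if (used_p[pi] || used_t[ti]) next
        used_p[pi] <- TRUE
        used_t[ti] <- TRUE
        keep_p <- c(keep_p, pi)
        keep_t <- c(keep_t, ti)
        keep_d <- c(keep_d, d[pi, ti] * mpp)
      }
      pairs <- tibble::tibble(pred_idx = as.integer(unname(keep_p)),
                              truth_idx = as.integer(unname(keep_t)),
                              distance_um = unname(keep_d))
    }
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = np - tp, fn = nt - tp, pairs = pairs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> TP ", x$tp, ", FP ", x$fp, ", FN ", x$fn, "\n", sep = "")
  invisible(x)
}

#' @rdname match_detections
#' @param x A `match_result`.
#' @param ... Unused.
#' @method glance match_result
#' @export
glance.match_result <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn,
                 precision = if (x$tp + x$fp > 0) precision(x$tp, x$fp) else NA_real_,
                 sensitivity = if (x$tp + x$fn > 0) sensitivity(x$tp, x$fn) else NA_real_)
}

#' Precision (positive predictive value)
#'
#' `TP / (TP + FP)`: the fraction of predicted mitoses that are real.
#'
#' @param tp,fp True-positive and false-positive counts.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' precision(67, 7)   # ~0.905
precision <- function(tp, fp) {
  if (tp + fp < 1) {
    abort("precision undefined: no predictions (tp + fp = 0)",
          class = "mitoquant_value_error")
  }
  tp / (tp + fp)
}

#' Sensitivity (recall)
#'
#' `TP / (TP + FN)`: the fraction of true mitoses that were detected.
#'
#' @param tp,fn True-positive and false-negative counts.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' sensitivity(67, 21)   # ~0.761
sensitivity <- function(tp, fn) {
  if (tp + fn < 1) {
    abort("sensitivity undefined: no truth points (tp + fn = 0)",
          class = "mitoquant_value_error")
  }
  tp / (tp + fn)
}

#' Bootstrap summary of a metric vector
#'
#' Resamples the supplied values with replacement (`reps` resamples, each of
#' the full sample size) and summarises the distribution of resample means:
#' the bootstrap mean, its SD, and the 2.5/97.5 percentile interval. The
#' resampling unit is whatever the caller supplies — per-reader metrics,
#' per-replicate group metrics, per-image scores.
#'
#' @param values Numeric vector, non-empty.
#' @param reps Number of resamples (default 10000).
#' @param seed Optional integer seed; summaries are reproducible under it.
#' @return An object of class `metric_summary`: `mean`, `sd`,
#'   `ci95 = c(lo, hi)`, `reps`, `seed`.
#' @export
bootstrap_ci <- function(values, reps = 10000, seed = NULL) {
  if (length(values) == 0) {
    abort("cannot bootstrap an empty vector", class = "mitoquant_value_error")
  }
  if (reps < 1) abort("reps must be >= 1", class = "mitoquant_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  means <- vapply(seq_len(reps),
                  function(i) mean(values[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  ci <- quantile(means, c(0.025, 0.975), names = FALSE)
  structure(list(mean = mean(means), sd = sd(means), ci95 = ci,
                 reps = reps, seed = seed),
            class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  cat("<metric_summary> mean ", signif(x$mean, 4), " (SD ", signif(x$sd, 3),
      "), CI95 [", signif(x$ci95[1], 4), ", ", signif(x$ci95[2], 4),
      "], ", x$reps, " resamples\n", sep = "")
  invisible(x)
}

#' Per-annotator evaluation table
#'
#' Scores each annotator's marks against ground truth and returns one row per
#' annotator — the table consumed by downstream significance tests and by
#' [bootstrap_ci()].
#'
#' @param annotations Data frame of marks (`x`, `y`, `annotator`).
#' @param truth Data frame of ground-truth points.
#' @param radius_um,mpp Matching radius and resolution.
#' @return A tibble: `annotator`, `tp`, `fp`, `fn`, `precision`, `sensitivity`.
#' @export
evaluate_annotators <- function(annotations, truth, radius_um = 15, mpp = 0.25) {
  pts <- as_point_tibble(annotations)
  split(pts, pts$annotator) |>
    purrr::imap(function(marks, id) {
      m <- match_detections(marks, truth, radius_um = radius_um, mpp = mpp)
      tibble::tibble(
        annotator = id, tp = m$tp, fp = m$fp, fn = m$fn,
        precision = if (m$tp + m$fp > 0) precision(m$tp, m$fp) else NA_real_,
        sensitivity = if (m$tp + m$fn > 0) sensitivity(m$tp, m$fn) else NA_real_
      )
    }) |>
    dplyr::bind_rows()
}
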