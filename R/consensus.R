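#' Cluster multi-annotator point detections into candidates
#'
#' Pools the points of all annotators and groups marks of the same putative
#' mitosis by single-linkage clustering at the matching radius: two marks
#' belong to the same candidate when they are connected by a chain of
#' within-radius links. Each annotator contributes at most one vote per
#' candidate, however many marks of theirs fall inside it; the representative
#' location is the centroid of the member marks.
#'
#' Single linkage can chain marks further than `2 * radius_um` apart into one
#' candidate when intermediate marks bridge them; with well-separated mitoses
#' this does not arise, but it is a property to keep in mind on dense slides.
#'
#' @param annotations Data frame of points with columns `x`, `y` (pixels) and
#'   `annotator`; one row per mark.
#' @param radius_um Linkage radius in micrometres (default 15, the evaluation
#'   radius).
#' @param mpp Micrometres per pixel (default 0.25, so 15 um = 60 px).
#' @return A tibble of class `candidate_clusters`, one row per candidate:
#'   `cluster`, `x`, `y` (centroid), `votes` (distinct annotators), `members`
#'   (list-column of member tibbles).
#' @export
cluster_annotations <- function(annotations, radius_um = 15, mpp = 0.25) {
  if (radius_um <= 0 || mpp <= 0) {
    abort("radius_um and mpp must be positive", class = "mitoquant_parameter_error")
  }
  pts <- as_point_tibble(annotations)
  if (nrow(pts) == 0) {
    out <- tibble::tibble(cluster = integer(), x = double(), y = double(),
                          votes = integer(), members = list())
    class(out) <- c("candidate_clusters", class(out))
    return(out)
  }
  radius_px <- radius_um / mpp
  if (nrow(pts) == 1) {
    cl <- 1L
  } else {
    hc <- hclust(dist(cbind(pts$x, pts$y)), method = "single")
    cl <- cutree(hc, h = radius_px)
  }
  out <- pts |>
    dplyr::mutate(cluster = cl) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      members = list(dplyr::pick("annotator", "x", "y")),
      votes = dplyr::n_distinct(.data$annotator),
      x = mean(.data$x), y = mean(.data$y),
      .groups = "drop"
    ) |>
    dplyr::select("cluster", "x", "y", "votes", "members")
  class(out) <- c("candidate_clusters", class(out))
  out
}

#' Majority-vote consensus of a reader group
#'
#' Keeps exactly the candidates marked by more than `k/2` of the `k` readers
#' (a strict majority, hence the odd group size) and returns their
#' representative points as the group's mitosis decision.
#'
#' @param clusters Output of [cluster_annotations()].
#' @param k Number of readers in the group; must be odd.
#' @return A tibble of consensus points: `x`, `y`, `votes`.
#' @export
#' @examples
#' ann <- data.frame(x = c(100, 101, 102, 900), y = 0,
#'                   annotator = c("a", "b", "c", "a"))
#' majority_vote(cluster_annotations(ann), k = 3)
majority_vote <- function(clusters, k) {
  if (k < 1 || k %% 2 == 0) {
    abort("k must be an odd number of annotators", class = "mitoquant_parameter_error")
  }
  kept <- dplyr::filter(tibble::as_tibble(clusters), .data$votes > k / 2)
  tibble::tibble(x = kept$x, y = kept$y, votes = kept$votes)
}

#' Per-candidate agreement rates
#'
#' The agreement rate of a candidate is the percentage of readers who marked
#' it. When ground truth is supplied, candidates are split into those matching
#' a true mitosis and false-positive candidates; following the convention that
#' only co-localized errors are of interest, false-positive candidates are
#' reported only when more than `fp_min_votes` readers agreed on them.
#'
#' @param clusters Output of [cluster_annotations()].
#' @param n_annotators Total number of readers (the denominator).
#' @param truth Optional data frame of ground-truth points (`x`, `y`).
#' @param radius_um,mpp Matching radius and resolution used to decide whether
#'   a candidate hits a true mitosis.
#' @param fp_min_votes False-positive candidates with `votes <= fp_min_votes`
#'   are dropped when `truth` is given (default 3, i.e. keep those "more than
#'   three" readers agreed on).
#' @return A tibble: `cluster`, `x`, `y`, `votes`, `rate_pct`, and (when
#'   `truth` is given) `group` in `{"ground_truth", "false_positive"}`.
#' @export
agreement_rates <- function(clusters, n_annotators, truth = NULL,
                            radius_um = 15, mpp = 0.25, fp_min_votes = 3) {
  if (n_annotators < 1) {
    abort("n_annotators must be >= 1", class = "mitoquant_parameter_error")
  }
  out <- tibble::as_tibble(clusters)[c("cluster", "x", "y", "votes")]
  out$rate_pct <- 100 * out$votes / n_annotators
  if (!is.null(truth)) {
    m <- match_detections(out, truth, radius_um = radius_um, mpp = mpp)
    matched <- logical(nrow(out))
    if (nrow(m$pairs) > 0) matched[m$pairs$pred_idx] <- TRUE
    out$group <- ifelse(matched, "ground_truth", "false_positive")
    out <- dplyr::filter(out, .data$group == "ground_truth" |
                           .data$votes > fp_min_votes)
  }
  out
}

#' Group-size consensus experiment
#'
#' For each group size, repeatedly samples that many readers uniformly without
#' replacement from the pool, forms the group's majority-vote consensus, and
#' scores it against ground truth with radius-based one-to-one matching. This
#' is the experiment behind the headline claim that small reader groups beat
#' the average individual reader.
#'
#' @param annotations Data frame of all readers' marks (`x`, `y`, `annotator`).
#' @param truth Data frame of ground-truth mitosis points.
#' @param sizes Odd group sizes to test (default `seq(3, 37, by = 2)`).
#' @param reps Replicates per size (default 100).
#' @param radius_um,mpp Matching radius (micrometres) and resolution.
#' @param seed Optional master seed; per-replicate streams are derived from it.
#' @return A tibble of class `group_experiment`, one row per (size, replicate):
#'   `group_size`, `replicate`, `tp`, `fp`, `fn`, `precision`, `sensitivity`.
#' @export
group_sampling_experiment <- function(annotations, truth,
                                      sizes = seq(3, 37, by = 2), reps = 100,
                                      radius_um = 15, mpp = 0.25, seed = NULL) {
  pts <- as_point_tibble(annotations)
  pool <- unique(pts$annotator)
  if (any(is.na(pool))) {
    abort("all annotation rows need an annotator id", class = "mitoquant_parameter_error")
  }
  if (any(sizes %% 2 == 0) || any(sizes < 1)) {
    abort("group sizes must be odd and positive", class = "mitoquant_parameter_error")
  }
  if (max(sizes) > length(pool)) {
    abort("largest group size exceeds the annotator pool", class = "mitoquant_parameter_error")
  }
  if (reps < 1) abort("reps must be >= 1", class = "mitoquant_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, length(sizes) * reps)
  by_annot <- split(pts, pts$annotator)
  rows <- list()
  idx <- 0L
  for (k in sizes) {
    for (r in seq_len(reps)) {
      idx <- idx + 1L
      set.seed(rep_seeds[idx])
      group <- sample(pool, k, replace = FALSE)
      marks <- dplyr::bind_rows(by_annot[group])
      consensus <- majority_vote(cluster_annotations(marks, radius_um, mpp), k)
      m <- match_detections(consensus, truth, radius_um = radius_um, mpp = mpp)
      rows[[idx]] <- tibble::tibble(
        group_size = k, replicate = r, tp = m$tp, fp = m$fp, fn = m$fn,
        precision = if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else NA_real_,
        sensitivity = if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else NA_real_
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  class(out) <- c("group_experiment", class(out))
  out
}

#' Summarise a group-size experiment
#'
#' @param x A `group_experiment` tibble.
#' @param ... Unused.
#' @return One row per group size with the mean and SD of precision and
#'   sensitivity over replicates.
#' @method glance group_experiment
#' @export
glance.group_experiment <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$group_size) |>
    dplyr::summarise(
      precision_mean = mean(.data$precision, na.rm = TRUE),
      precision_sd = sd(.data$precision, na.rm = TRUE),
      sensitivity_mean = mean(.data$sensitivity, na.rm = TRUE),
      sensitivity_sd = sd(.data$sensitivity, na.rm = TRUE),
      reps = dplyr::n(),
      .groups = "drop"
    )
}
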