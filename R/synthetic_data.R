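#' Specification of a synthetic slide
#'
#' Describes a simulated whole-slide mitosis point pattern: a homogeneous
#' Poisson background plus Gaussian hotspots, the structure that makes hotspot
#' quantifiers diverge from slide averages. The defaults describe a 20 x 20
#' HPF slide (32 mm^2 of tissue) with a low diffuse mitotic rate and three
#' hotspots of decreasing intensity — a mid-range proliferative meningioma.
#'
#' @param extent `(width, height)` of the slide in pixels.
#' @param hotspots Data frame with columns `x`, `y` (center, pixels),
#'   `spread_px` (isotropic Gaussian SD) and `n_expected` (Poisson mean count).
#' @param background_rate Expected mitoses per HPF area outside hotspots.
#' @param hpf_edge_px HPF edge used to scale `background_rate` (default 1600).
#' @param exclusion Optional `region_mask` carried through to the output.
#' @param seed Optional integer seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(extent = c(32000, 32000),
                     hotspots = default_hotspots(extent),
                     background_rate = 0.2, hpf_edge_px = 1600,
                     exclusion = NULL, seed = NULL) {
  if (background_rate < 0 || (!is.null(hotspots) && any(hotspots$n_expected < 0))) {
    abort("rates must be non-negative", class = "mitoquant_parameter_error")
  }
  if (!is.null(hotspots) && nrow(hotspots) > 0 &&
      (any(hotspots$x < 0 | hotspots$x > extent[1]) ||
       any(hotspots$y < 0 | hotspots$y > extent[2]))) {
    abort("hotspot centers must lie within the extent", class = "mitoquant_parameter_error")
  }
  structure(list(extent = as.numeric(extent), hotspots = hotspots,
                 background_rate = background_rate, hpf_edge_px = hpf_edge_px,
                 exclusion = exclusion, seed = seed),
            class = "sim_spec")
}

#' @rdname sim_spec
#' @export
default_hotspots <- function(extent = c(32000, 32000)) {
  tibble::tibble(
    x = extent[1] * c(0.30, 0.62, 0.75),
    y = extent[2] * c(0.35, 0.55, 0.20),
    spread_px = c(2000, 1600, 1200),
    n_expected = c(60, 30, 15)
  )
}

#' Simulate a synthetic slide
#'
#' Draws background mitoses from a homogeneous Poisson process at
#' `background_rate` per HPF area and adds, for each hotspot, a
#' Poisson-distributed number of points with isotropic Gaussian spread around
#' its center. Points falling outside the extent are dropped (truncated
#' tails). Reproducible under the spec's seed.
#'
#' @param spec A [sim_spec()].
#' @return A list with `points` (tibble `x`, `y`, `annotator = NA`,
#'   `label = "mitosis"`) and `mask` (the spec's exclusion mask, possibly
#'   `NULL`).
#' @export
simulate_wsi <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  w <- spec$extent[1]
  h <- spec$extent[2]
  n_hpf <- (w * h) / spec$hpf_edge_px^2
  n_bg <- rpois(1, spec$background_rate * n_hpf)
  xs <- runif(n_bg, 0, w)
  ys <- runif(n_bg, 0, h)
  if (!is.null(spec$hotspots) && nrow(spec$hotspots) > 0) {
    for (i in seq_len(nrow(spec$hotspots))) {
      hs <- spec$hotspots[i, ]
      n <- rpois(1, hs$n_expected)
      xs <- c(xs, rnorm(n, hs$x, hs$spread_px))
      ys <- c(ys, rnorm(n, hs$y, hs$spread_px))
    }
  }
  keep <- xs >= 0 & xs < w & ys >= 0 & ys < h
  list(points = tibble::tibble(x = xs[keep], y = ys[keep],
                               annotator = NA_character_, label = "mitosis"),
       mask = spec$exclusion)
}

#' Simulated annotator error model
#'
#' An annotator marks each true mitosis independently with probability
#' `sensitivity` and each decoy site (a mitosis-mimicking nucleus shared
#' across annotators, so false positives can co-localize) with probability
#' `fp_rate`; every kept mark is displaced by isotropic Gaussian jitter.
#' The defaults emulate a mid-level reader: sensitivity 0.667 and a decoy
#' mark rate calibrated so that, over the default reader-study geometry
#' (88 true mitoses, 97 decoys), individual precision is about 0.75.
#'
#' @param sensitivity Probability of marking a true mitosis, in `[0, 1]`.
#' @param fp_rate Probability of marking each decoy site, in `[0, 1]`.
#' @param jitter_sigma_um Localization noise SD in micrometres (>= 0).
#' @return An object of class `annotator_model`.
#' @export
annotator_model <- function(sensitivity = 0.667, fp_rate = 0.2,
                            jitter_sigma_um = 0) {
  if (sensitivity < 0 || sensitivity > 1 || fp_rate < 0 || fp_rate > 1 ||
      jitter_sigma_um < 0) {
    abort("invalid annotator model parameters", class = "mitoquant_parameter_error")
  }
  structure(list(sensitivity = sensitivity, fp_rate = fp_rate,
                 jitter_sigma_um = jitter_sigma_um),
            class = "annotator_model")
}

#' Simulate one annotator's marks
#'
#' @param truth Data frame of true mitosis points.
#' @param decoys Data frame of decoy sites (may have 0 rows).
#' @param model An [annotator_model()].
#' @param annotator_id Id stored in the output's `annotator` column.
#' @param mpp Micrometres per pixel (converts jitter to pixels).
#' @param seed Optional integer seed.
#' @return A tibble of marks (`x`, `y`, `annotator`, `label`), where `label`
#'   records whether the mark came from a true mitosis or a decoy.
#' @export
simulate_annotator <- function(truth, decoys = NULL, model = annotator_model(),
                               annotator_id = "sim", mpp = 0.25, seed = NULL) {
  stopifnot(inherits(model, "annotator_model"))
  if (!is.null(seed)) set.seed(seed)
  truth <- as_point_tibble(truth)
  decoys <- if (is.null(decoys)) truth[0, ] else as_point_tibble(decoys)
  kept_t <- truth[runif(nrow(truth)) < model$sensitivity, ]
  kept_d <- decoys[runif(nrow(decoys)) < model$fp_rate, ]
  out <- dplyr::bind_rows(
    dplyr::mutate(kept_t, label = "true"),
    dplyr::mutate(kept_d, label = "decoy")
  )
  if (nrow(out) > 0 && model$jitter_sigma_um > 0) {
    s <- model$jitter_sigma_um / mpp
    out$x <- out$x + rnorm(nrow(out), 0, s)
    out$y <- out$y + rnorm(nrow(out), 0, s)
  }
  out$annotator <- annotator_id
  out
}

#' Simulate a pool of independent annotators
#'
#' All annotators share the same truth and decoy sites (so their false
#' positives can co-localize, which is what makes agreement-rate analysis of
#' false positives possible) but make independent marking decisions.
#'
#' @param truth,decoys Point data frames shared across the pool.
#' @param n_annotators Pool size.
#' @param model An [annotator_model()] applied to every annotator.
#' @param mpp Micrometres per pixel.
#' @param seed Optional master seed; per-annotator streams are derived.
#' @return A tibble of all marks with `annotator` ids `"r01"`, `"r02"`, ...
#' @export
simulate_annotator_pool <- function(truth, decoys = NULL, n_annotators = 41,
                                    model = annotator_model(), mpp = 0.25,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_annotators)
  purrr::map(seq_len(n_annotators), function(i) {
    simulate_annotator(truth, decoys, model,
                       annotator_id = sprintf("r%02d", i),
                       mpp = mpp, seed = seeds[i])
  }) |>
    dplyr::bind_rows()
}

#' Simulate a reader study
#'
#' Builds the full input of the consensus experiments: well-separated true
#' mitosis and decoy sites on a multi-HPF canvas, plus a pool of independent
#' simulated annotators. Sites are placed uniformly under a hard-core minimum
#' separation (default 40 um, i.e. more than twice the 15 um matching radius)
#' so each site forms its own candidate cluster — distinct nuclei do not
#' overlap within a matching radius. The default geometry mirrors a 48-HPF
#' reading session with 88 true mitoses and 97 plausible mimics.
#'
#' @param n_truth,n_decoys Numbers of true and decoy sites.
#' @param extent Canvas `(width, height)` in pixels; default 8 x 6 HPFs.
#' @param n_annotators Pool size (default 41).
#' @param model An [annotator_model()].
#' @param min_sep_um Minimum separation between any two sites, micrometres.
#' @param mpp Micrometres per pixel.
#' @param seed Optional master seed.
#' @return A list with `truth`, `decoys` (point tibbles) and `annotations`
#'   (the pooled annotator marks).
#' @export
simulate_reader_study <- function(n_truth = 88, n_decoys = 97,
                                  extent = c(12800, 9600), n_annotators = 41,
                                  model = annotator_model(), min_sep_um = 40,
                                  mpp = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sites <- hardcore_sites(n_truth + n_decoys, extent, min_sep_um / mpp)
  truth <- sites[seq_len(n_truth), ]
  decoys <- sites[n_truth + seq_len(n_decoys), ]
  pool_seed <- sample.int(.Machine$integer.max, 1)
  ann <- simulate_annotator_pool(truth, decoys, n_annotators, model,
                                 mpp = mpp, seed = pool_seed)
  list(truth = truth, decoys = decoys, annotations = ann)
}

# Uniform sites under a hard-core minimum separation, by dart throwing.
hardcore_sites <- function(n, extent, min_sep_px, max_tries = 200 * n) {
  xs <- numeric(0)
  ys <- numeric(0)
  tries <- 0
  while (length(xs) < n && tries < max_tries) {
    tries <- tries + 1
    x <- runif(1, 0, extent[1])
    y <- runif(1, 0, extent[2])
    if (length(xs) == 0 || min((xs - x)^2 + (ys - y)^2) >= min_sep_px^2) {
      xs <- c(xs, x)
      ys <- c(ys, y)
    }
  }
  if (length(xs) < n) {
    abort("could not place that many separated sites in the extent",
          class = "mitoquant_sampling_error")
  }
  tibble::tibble(x = xs, y = ys, annotator = NA_character_, label = NA_character_)
}

#' Exact majority-vote rates for independent readers
#'
#' Under independence, a group of `k` readers keeps a true mitosis that each
#' reader marks with probability `p` exactly when more than `k/2` of them mark
#' it; the group sensitivity is `P(Binomial(k, p) > k/2)`, and likewise the
#' false-keep rate for a decoy marked with probability `q`. For `q < 0.5` and
#' `k >= 3` the false-keep rate is strictly below `q` — the mechanism by which
#' majority voting suppresses independent false positives.
#'
#' @param p Per-reader probability of marking a true mitosis.
#' @param q Per-reader probability of marking a decoy.
#' @param k Group size; must be odd.
#' @return Named numeric: `sensitivity`, `false_keep`.
#' @export
#' @examples
#' expected_group_rates(0.7, 0.1, 3)   # 0.784, 0.028
expected_group_rates <- function(p, q, k) {
  if (k < 1 || k %% 2 == 0) {
    abort("k must be odd", class = "mitoquant_parameter_error")
  }
  if (any(c(p, q) < 0) || any(c(p, q) > 1)) {
    abort("p and q must be probabilities", class = "mitoquant_parameter_error")
  }
  need <- (k + 1) / 2   # "more than k/2" for odd k
  c(sensitivity = 1 - stats::pbinom(need - 1, k, p),
    false_keep = 1 - stats::pbinom(need - 1, k, q))
}
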