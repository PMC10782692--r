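---
title: "Mitotic count quantification and reader consensus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitotic count quantification and reader consensus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

The mitotic count (MC) — mitoses per 10 consecutive high-power fields (HPFs)
taken from the area of highest mitotic activity — is a grading criterion for
meningioma and many other tumors. On a glass slide the "10 consecutive HPFs"
are wherever the pathologist steers the stage; on a whole-slide image (WSI)
they can be defined exactly. This package formalizes that definition and
answers two questions: *what is the mathematically maximal MC a slide
supports*, and *how should several readers' mitosis detections be combined
into one decision*.

## The HPF grid

A WSI is tiled into non-overlapping square cells of edge `hpf_edge_px`
pixels. At the default 0.25 µm/px resolution a 1600 px cell is
400 µm × 400 µm = 0.16 mm², the standardized HPF area. Cells are half-open,
`[k·edge, (k+1)·edge)` in each axis, so every point — including one exactly
on a cell border — belongs to exactly one cell.

Two parameters deserve attention:

* **`origin_offset`** — the tiling anchor is arbitrary: nothing privileges
  pixel (0, 0). Shifting the anchor within one cell edge re-cuts every cell
  and changes every per-cell count. We expose the offset as a first-class
  parameter and provide `origin_shift_scan()` to quantify the sensitivity;
  the per-method maximum over a scan is itself a useful, slightly more
  anchor-free statistic. The default offset is (0, 0).
* **`eligibility_min_fraction`** — background, out-of-focus and non-tumor
  regions (supplied as polygon or raster masks; detecting them is out of
  scope here) must not contribute fields. A cell is *eligible* iff the
  fraction of its area free of excluded regions is at least this value. The
  default 0.99 means a cell must be essentially mask-free, the closest
  reading of "excluded outright" that still tolerates rasterization noise at
  region borders. Points landing in ineligible cells stay in the data (they
  are reported in slide totals) but contribute to no hotspot quantity.

Polygon–cell overlap is computed exactly (Sutherland–Hodgman clipping of the
polygon by the cell rectangle, shoelace area) when a single polygon touches
the cell; when several excluded polygons overlap one cell their union is
estimated on a 32 × 32 midpoint subgrid, since summed clip areas would
double-count overlaps. The tests cross-check both routes against an
independent fine point-in-polygon rasterization.

## Six quantifiers of the hotspot MC

Let `c(r, k)` be the mitosis count of cell (r, k) and consider only eligible
cells.

1. **DFS path maximum** (`dfs_max_path()`): the maximum of
   `sum(c over P)` over all *simple paths* `P` of `L = 10` cells — pairwise
   distinct, each consecutive pair sharing an edge (4-neighborhood; diagonal
   contact does not connect). This is the flexible-shape reading of "10
   consecutive HPFs": any snake the stage could trace, not just a straight
   bar or a block.
2. **Linear windows**: best 10 × 1 and 1 × 10 window sums.
3. **Rectangular windows**: best 5 × 2 and 2 × 5 window sums.
4. **Average per 10 HPFs**: `10 · Σc / (number of eligible cells)`.
5. **Random 10 HPFs** (`random_mc_distribution()`): distribution of the sum
   over 10 eligible cells drawn uniformly without replacement; its mean is
   the hypergeometric expectation `10 · mean(c)`, which the tests verify.
6. **Top-10 unconnected** (`top_k_unconnected()`): sum of the ten largest
   cell counts — the unconstrained upper bound.

Every 10 × 1, 1 × 10, 5 × 2 or 2 × 5 window admits a Hamiltonian snake
traversal, so the domination chain

> top-10 unconnected ≥ DFS path ≥ every window maximum

holds for any input, and the test suite asserts it on every fixture. Windows
covering an ineligible cell are skipped entirely, mirroring the path rule.

Note one subtlety of masking: adding an exclusion region can only lower the
count-based quantities (1–3, 6), but the *average* (4) may rise when the
removed cells are below the slide mean — it is a ratio, not a count.

### Exactness and pruning

`dfs_max_path()` is a recursive depth-first search with backtracking over
all simple L-paths, implemented in C++. Pruning is *admissible only*: a
branch is abandoned when its running sum plus the sum of the `L − depth`
largest eligible counts on the whole grid cannot beat the incumbent, which
never discards an optimal path. Start cells are visited in descending order
of the count mass within Manhattan radius `L − 1`, so a near-optimal
incumbent is found early and pruning bites; ties in this ordering, and the
neighbor order North–East–South–West with strictly-improving incumbent
updates, make the returned path deterministic. A path and its reverse are
one solution (the canonical orientation puts the smaller row-major endpoint
first). `brute_force_max_path()` — plain enumeration in R, refusing grids
over 36 cells — is kept in the package as the independent oracle the test
suite compares against.

If fewer than `L` eligible cells exist, or no simple `L`-path survives the
eligibility holes, the result reports `found = FALSE` with an `NA` count —
deliberately distinguishable from a genuine count of 0 on an empty but
traversable slide. A slide with no annotated mitoses at all reports 0 under
every method and MC-only grade 1.

### Grading

`grade_from_mc()` maps an MC to the grade supported by the mitotic-count
criterion alone: grade 2 at ≥ 4, grade 3 at ≥ 20 mitoses/10 HPFs (the CNS
WHO thresholds; configurable). The output is labeled MC-criterion-only
because a real WHO grade integrates criteria this package does not see.

## Reader consensus by majority vote

Readers mark mitoses as points. To combine `k` readers (odd by
construction):

1. **Candidate formation** (`cluster_annotations()`): pooled marks are
   grouped by single-linkage clustering at the matching radius (15 µm =
   60 px by default). Single linkage at the evaluation radius is the minimal
   assumption consistent with the matching rule below; it can chain marks
   further than 2 × radius apart through intermediaries, which is accepted
   and documented rather than patched. One reader casts at most one vote per
   candidate regardless of double-marking; the representative point is the
   member centroid (deterministic and order-free, unlike a medoid).
2. **Majority vote** (`majority_vote()`): candidates with votes `> k/2` are
   the group's decision. For independent readers with true-detection
   probability `p` and per-decoy mark probability `q`,
   `expected_group_rates()` gives the exact binomial group operating point
   `P(Bin(k, p) > k/2)` / `P(Bin(k, q) > k/2)`; for `q < 0.5`, `k ≥ 3` the
   false-keep rate is strictly below `q` — majority voting suppresses
   independent false positives while roughly preserving sensitivity near
   `p = 0.7`. This is the mechanism behind the precision gain of small
   reader groups, and the simulation tests verify the empirical rates
   against these closed forms.
3. **Group-size experiment** (`group_sampling_experiment()`): for each odd
   size, groups are drawn uniformly without replacement from the pool (100
   replicates per size by default), scored against ground truth, and
   summarised per size.

## Evaluation

`match_detections()` scores predictions against ground truth by one-to-one
greedy matching on ascending distance among all pairs within the radius
(inclusive: exactly 15 µm counts, so boundary annotations are not dropped);
remaining ties break on (truth index, prediction index). One-to-one matching
is chosen over the literal "a TP is a mitosis within 15 µm of an annotation"
because the literal reading double-counts — two marks on one mitosis would
both be TPs — and breaks the conservation laws `tp + fp = |pred|`,
`tp + fn = |truth|` on which precision and sensitivity rest. Precision is
`TP/(TP+FP)`, sensitivity `TP/(TP+FN)`. `bootstrap_ci()` resamples a metric
vector with replacement (10,000 resamples by default) and reports the mean,
SD and 2.5/97.5 percentile interval of the resample means; the resampling
unit is whatever vector the caller supplies (per-reader metrics,
per-replicate group metrics, ...), since no single unit is canonical.

## The synthetic-data generator

No external dataset ships with the package; everything is exercised on
synthetic data whose generator is itself part of the tested surface.

* `simulate_wsi()` draws a homogeneous Poisson background (default 0.2
  mitoses per HPF) plus Gaussian hotspots (defaults: three hotspots of
  expected mass 60/30/15 with spreads 2000/1600/1200 px on a 20 × 20-HPF
  slide). These defaults were chosen once to represent a mid-range
  proliferative meningioma — total burden in the low hundreds against a
  sparse background, with one dominant and two secondary hotspots — and give
  the hotspot-seeking quantifiers something real to disagree about.
* `simulate_annotator()` keeps each true mitosis with probability `p`
  (default 0.667, a mid-level reader's sensitivity) and marks each *decoy*
  — a mitosis-mimicking site from a shared list — with probability `q`
  (default 0.2, calibrated so that with 88 true and 97 decoy sites an
  individual's precision is about 0.75). Decoys are shared across the pool
  so false positives can co-localize, which is exactly what agreement-rate
  analysis of false positives needs; readers' decisions are otherwise
  independent. Optional Gaussian jitter models localization noise.
* `simulate_reader_study()` places the sites uniformly under a 40 µm
  hard-core separation (distinct nuclei do not sit within one matching
  radius of each other), so each site forms its own candidate cluster when
  jitter is small.

What the generator deliberately does *not* model: correlated reader errors
(real pathologists miss the same hard cases together, which lowers group
gains below the independent-reader prediction), reader-specific skill
spread, annotator fatigue, and any image content. Passing tests therefore
demonstrate the algorithms' correctness and the voting mechanism's
arithmetic, not field performance of reader groups.

## Numerical choices and degenerate inputs

* All radii are specified in µm and converted once via `microns_per_px`;
  distances are Euclidean in the pixel frame.
* Inclusive radius comparisons throughout (matching and linkage).
* Window and path ties resolve to the first optimum in row-major order —
  outputs are reproducible run to run.
* Degenerate cases are explicit errors, not silent zeros: precision with no
  predictions, sensitivity with no truth, averages with no eligible cells,
  sampling more fields than exist, even group sizes, offsets outside
  `[0, edge)`.
* Every stochastic routine takes a seed and derives independent
  sub-streams from it; no function depends on ambient RNG state for its
  defaults.

## Problem sizes in the test suite

The suite verifies the DFS against brute-force enumeration on 60 random
grids up to 5 × 5 (path lengths up to 6, plus 4 × 4 at length 10), checks
the domination chain and masking monotonicity on clustered fixtures of ~100
points, runs the consensus experiment with a 41-reader pool on 200 true /
300 decoy sites over 200 group-of-3 replicates against the exact binomial
prediction, and validates the random-field quantifier at 1,000 draws against
its hypergeometric mean. These sizes keep the whole suite under a minute on
a laptop while leaving each check statistically sharp (tolerances are stated
as multiples of the relevant Monte-Carlo standard error, not absolute
fudge factors).

## Known limitations

* The DFS is exact but exponential in the worst case; admissible pruning
  makes real, hotspot-structured slides fast (hotspots give strong
  incumbents early), but a pathological near-uniform grid with thousands of
  cells can be slow. The search never trades exactness for speed.
* Plus-shaped and other non-snake 10-cell regions admit no simple path and
  are thus never reported; a maximum over arbitrary connected regions is a
  different (harder) problem and out of scope by design.
* Single-linkage chaining can merge distinct candidates on very dense
  annotations (inter-mitosis spacing below the matching radius).
* Masks are inputs; nothing here segments tissue.
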