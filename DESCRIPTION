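Package: mitoquant
Title: Mitotic Count Quantification and Multi-Reader Consensus for Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing mitotic activity on digitized pathology slides.
    Partitions a whole-slide image into high-power fields (HPFs), bins mitosis
    point annotations into the grid, and quantifies the hotspot mitotic count
    per 10 HPFs by six methods, centred on an exact depth-first search with
    backtracking for the maximum-count simple path of 10 edge-connected HPFs.
    Also implements majority-vote consensus over multiple annotators' point
    detections, radius-based one-to-one precision/sensitivity evaluation with
    bootstrap confidence intervals, and a synthetic-slide / simulated-annotator
    generator so every component is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    mgcv,
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
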