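# Shared fixtures, all generated in code.

# axis-aligned square polygon as a vertex matrix
square_poly <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

# a clustered point pattern with a known dense hotspot plus sparse background,
# deterministic under seed
clustered_points <- function(seed = 11, edge = 100) {
  set.seed(seed)
  hot <- tibble::tibble(x = rnorm(60, 5.5 * edge, 1.2 * edge),
                        y = rnorm(60, 4.5 * edge, 1.2 * edge))
  bg <- tibble::tibble(x = runif(40, 0, 12 * edge), y = runif(40, 0, 10 * edge))
  pts <- dplyr::bind_rows(hot, bg)
  pts[pts$x >= 0 & pts$y >= 0, ]
}

# random small grid with Poisson counts
random_grid <- function(seed, nr = 4, nc = 4, lambda = 2) {
  set.seed(seed)
  hpf_grid(matrix(rpois(nr * nc, lambda), nr, nc))
}

# marks from k perfectly coincident annotators at the given sites
coincident_annotations <- function(sites, ids) {
  dplyr::bind_rows(lapply(ids, function(id) {
    out <- sites
    out$annotator <- id
    out
  }))
}

expect_path_valid <- function(res, grid, L) {
  expect_true(res$found)
  expect_silent(mitoquant:::validate_path_result(res, grid, L))
}
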