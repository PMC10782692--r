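test_that("binning follows the half-open floor rule and conserves points", {
  spec <- grid_spec(hpf_edge_px = 1600)
  g <- make_grid(data.frame(x = 0, y = 0), spec)
  expect_equal(as_tibble(g)$count[as_tibble(g)$row == 0 & as_tibble(g)$col == 0], 1L)
  # boundary point belongs to the next cell, not both
  g2 <- make_grid(data.frame(x = c(1600, 1599.999), y = c(0, 0)), spec)
  t2 <- as_tibble(g2)
  expect_equal(t2$count[t2$col == 0], 1L)
  expect_equal(t2$count[t2$col == 1], 1L)
  # conservation with several points per cell
  pts <- data.frame(x = c(10, 20, 30, 5000, 5100), y = c(10, 20, 30, 10, 20))
  g3 <- make_grid(pts, spec)
  expect_equal(sum(g3$counts), 5L)
  expect_equal(sort(g3$counts[g3$counts > 0]), c(2L, 3L))
})

test_that("point conservation holds for random patterns at any origin offset", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- data.frame(x = runif(200, 0, 20000), y = runif(200, 0, 15000))
    off <- runif(2, 0, 1599)
    g <- make_grid(pts, grid_spec(origin_offset = off))
    expect_equal(sum(g$counts), 200L)
  }
})

test_that("binning is translation-consistent", {
  set.seed(3)
  pts <- data.frame(x = runif(100, 0, 8000), y = runif(100, 0, 8000))
  g0 <- make_grid(pts, grid_spec())
  shifted <- data.frame(x = pts$x + 3200, y = pts$y + 1600)
  g1 <- make_grid(shifted, grid_spec())
  # same count multiset, displaced by whole cells
  expect_equal(sort(g0$counts[g0$counts > 0]), sort(g1$counts[g1$counts > 0]))
  expect_equal(sum(g1$counts), 100L)
})

test_that("points left of a shifted origin extend the grid instead of vanishing", {
  g <- make_grid(data.frame(x = c(100, 3000), y = c(100, 100)),
                 grid_spec(origin_offset = c(800, 800)))
  expect_equal(sum(g$counts), 2L)
  expect_equal(min(as_tibble(g)$row), -1L)   # y = 100 < dy = 800
})

test_that("shift_origin validates its range and changes only the offset", {
  spec <- grid_spec()
  s2 <- shift_origin(spec, 800, 400)
  expect_equal(s2$origin_offset, c(800, 400))
  expect_equal(s2$hpf_edge_px, spec$hpf_edge_px)
  expect_error(shift_origin(spec, 1600, 0), class = "mitoquant_parameter_error")
  expect_error(shift_origin(spec, -1, 0), class = "mitoquant_parameter_error")
  # zero shift reproduces identical binning
  pts <- clustered_points(seed = 5, edge = 1600)
  expect_equal(make_grid(pts, shift_origin(spec, 0, 0))$counts,
               make_grid(pts, spec)$counts)
})

test_that("eligibility: no mask keeps everything; engulfed cells drop out", {
  pts <- data.frame(x = c(100, 1700, 3300), y = rep(100, 3))
  g <- make_grid(pts, grid_spec())
  expect_true(all(g$eligible))
  # middle cell fully inside a non_tumor polygon
  mask <- mask_polygons(list(square_poly(1600, 0, 1600)))
  gm <- make_grid(pts, grid_spec(), mask)
  tm <- as_tibble(gm)
  expect_false(tm$eligible[tm$col == 1 & tm$row == 0])
  expect_true(all(tm$eligible[tm$col != 1]))
  # the engulfed point is retained in counts but flagged
  expect_equal(sum(gm$counts), 3L)
  expect_equal(gm$n_points_ineligible, 1L)
})

test_that("partial mask overlap respects min_fraction, agreeing with a rasterization oracle", {
  skip_if_not_installed("mgcv")
  # polygon covering 40% of cell (0,0): x in [0, 640) of a 1600 cell
  poly <- square_poly(0, 0, 1600)
  poly[, 1] <- poly[, 1] * 0.4
  mask <- mask_polygons(list(poly))
  spec <- grid_spec()
  spec$n_rows <- 1L
  spec$n_cols <- 1L
  expect_true(compute_eligibility(spec, mask, min_fraction = 0.5)[1, 1])
  expect_false(compute_eligibility(spec, mask, min_fraction = 0.7)[1, 1])

  # oracle: fine point-in-polygon rasterization of the same cell
  n <- 200
  xs <- (seq_len(n) - 0.5) / n * 1600
  grid_pts <- expand.grid(x = xs, y = xs)
  inside <- mgcv::in.out(rbind(poly, poly[1, ]), as.matrix(grid_pts))
  frac_oracle <- mean(inside)
  frac_exact <- mitoquant:::excluded_fraction_rect(mask, 0, 0, 1600, 1600)
  expect_equal(frac_exact, 0.4, tolerance = 1e-12)
  expect_equal(frac_oracle, frac_exact, tolerance = 0.01)
})

test_that("overlapping exclusion polygons are unioned, not double-counted", {
  # two half-cell rectangles overlapping in the middle: union covers 75%
  p1 <- square_poly(0, 0, 100); p1[, 1] <- p1[, 1] * 0.5        # left half
  p2 <- square_poly(25, 0, 100); p2[c(2, 3), 1] <- 75           # middle half
  mask <- mask_polygons(list(p1, p2))
  frac <- mitoquant:::excluded_fraction_rect(mask, 0, 0, 100, 100)
  expect_equal(frac, 0.75, tolerance = 0.02)
})

test_that("eligibility is monotone under growing exclusions", {
  pts <- clustered_points(seed = 7, edge = 1600)
  small <- mask_polygons(list(square_poly(3200, 3200, 1600)))
  big <- mask_polygons(list(square_poly(1600, 1600, 6400)))
  e_small <- make_grid(pts, grid_spec(), small)$eligible
  e_big <- make_grid(pts, grid_spec(), big)$eligible
  expect_true(all(e_big[!e_small] == FALSE))   # nothing ineligible becomes eligible
  expect_lte(sum(e_big), sum(e_small))
})
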