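test_that("dfs_max_path solves small worked examples exactly", {
  # unique Hamiltonian strip
  strip <- hpf_grid(matrix(1:10, 1))
  res <- dfs_max_path(strip, 10)
  expect_equal(res$count, 55)
  expect_path_valid(res, strip, 10)

  # 3x3 with an off-center optimum
  g <- hpf_grid(matrix(c(3, 0, 1, 2, 9, 1, 0, 4, 1), 3, byrow = TRUE))
  res3 <- dfs_max_path(g, 3)
  expect_equal(res3$count, 15)
  expect_setequal(paste(res3$cells$row, res3$cells$col),
                  c("2 1", "1 1", "1 0"))
  expect_path_valid(res3, g, 3)

  # all-zero grid still has a valid zero-count path
  z <- hpf_grid(matrix(0L, 5, 5))
  rz <- dfs_max_path(z, 10)
  expect_true(rz$found)
  expect_equal(rz$count, 0)
  expect_path_valid(rz, z, 10)
})

test_that("dfs reports no-path distinctly when the grid cannot host one", {
  # 9 eligible cells cannot host a 10-path
  r <- dfs_max_path(hpf_grid(matrix(1L, 3, 3)), 10)
  expect_false(r$found)
  expect_true(is.na(r$count))
  # eligibility can also sever all long paths
  elig <- matrix(TRUE, 1, 12)
  elig[1, 6] <- FALSE
  r2 <- dfs_max_path(hpf_grid(matrix(1L, 1, 12), elig), 10)
  expect_false(r2$found)
})

test_that("dfs equals the brute-force oracle over many random grids", {
  for (seed in 1:30) {
    nr <- sample(2:5, 1)
    nc <- sample(2:5, 1)
    g <- random_grid(seed, nr, nc, lambda = 2)
    L <- min(6, nr * nc)
    a <- dfs_max_path(g, L)
    b <- brute_force_max_path(g, L)
    expect_equal(a$found, b$found)
    if (a$found) {
      expect_equal(a$count, b$count)
      expect_path_valid(a, g, L)
    }
  }
  # longer paths on 4x4
  for (seed in 31:40) {
    g <- random_grid(seed, 4, 4, lambda = 3)
    a <- dfs_max_path(g, 10)
    b <- brute_force_max_path(g, 10)
    expect_equal(a$count, b$count)
  }
})

test_that("oracle equivalence holds under random eligibility holes", {
  for (seed in 1:15) {
    set.seed(seed)
    g <- hpf_grid(matrix(rpois(25, 2), 5),
                  matrix(runif(25) > 0.2, 5))
    a <- dfs_max_path(g, 5)
    b <- brute_force_max_path(g, 5)
    expect_equal(a$found, b$found)
    if (a$found) expect_equal(a$count, b$count)
  }
})

test_that("brute force refuses oversized grids", {
  expect_error(brute_force_max_path(hpf_grid(matrix(0L, 6, 7)), 5),
               class = "mitoquant_size_error")
})

test_that("max_window matches a direct sliding-scan oracle and skips ineligible cells", {
  expect_equal(max_window(hpf_grid(matrix(2L, 6, 6)), c(2, 5))$count, 20)
  expect_equal(max_window(hpf_grid(matrix(1:10, 1)), c(1, 10))$count, 55)
  set.seed(21)
  cnt <- matrix(rpois(72, 3), 8, 9)
  elig <- matrix(runif(72) > 0.15, 8, 9)
  g <- hpf_grid(cnt, elig)
  for (shape in list(c(1, 10), c(10, 1), c(2, 5), c(5, 2), c(3, 3))) {
    # oracle: enumerate all placements directly
    best <- -Inf
    if (nrow(cnt) >= shape[1] && ncol(cnt) >= shape[2]) {
      for (i in seq_len(nrow(cnt) - shape[1] + 1)) {
        for (j in seq_len(ncol(cnt) - shape[2] + 1)) {
          rows <- i:(i + shape[1] - 1); cols <- j:(j + shape[2] - 1)
          if (all(elig[rows, cols])) best <- max(best, sum(cnt[rows, cols]))
        }
      }
    }
    got <- max_window(g, shape)
    if (is.finite(best)) expect_equal(got$count, best) else expect_false(got$found)
  }
  # too-large window reports no placement
  expect_false(max_window(hpf_grid(matrix(1, 2, 2)), c(1, 10))$found)
})

test_that("average MC per 10 HPFs follows its formula and guards emptiness", {
  expect_equal(average_mc_per_10(hpf_grid(matrix(c(7, 0, 0, 0), 2))), 17.5)
  expect_equal(average_mc_per_10(hpf_grid(matrix(0L, 10, 10))), 0)
  g_all_masked <- hpf_grid(matrix(1L, 2, 2), matrix(FALSE, 2, 2))
  expect_error(average_mc_per_10(g_all_masked), class = "mitoquant_value_error")
})

test_that("random-field sampling is seeded, degenerate on uniform grids, and hypergeometric in mean", {
  u <- hpf_grid(matrix(3L, 10, 10))
  d <- random_mc_distribution(u, 10, reps = 100, seed = 1)
  expect_equal(d$mean, 30)
  expect_equal(d$sd, 0)
  expect_equal(d$ci95, c(30, 30))

  d1 <- random_mc_distribution(random_grid(5, 8, 8, 4), 10, reps = 200, seed = 9)
  d2 <- random_mc_distribution(random_grid(5, 8, 8, 4), 10, reps = 200, seed = 9)
  expect_identical(d1$draws, d2$draws)

  g <- random_grid(6, 10, 10, 2)
  reps <- 1000
  d3 <- random_mc_distribution(g, 10, reps = reps, seed = 2)
  vals <- g$counts[g$eligible]
  mu <- 10 * mean(vals)                 # hypergeometric expectation
  se <- d3$sd / sqrt(reps)              # Monte-Carlo standard error
  expect_lt(abs(d3$mean - mu), 4 * se)
  expect_lte(max(d3$draws), top_k_unconnected(g, 10))
  expect_error(random_mc_distribution(hpf_grid(matrix(1, 2, 2)), 10),
               class = "mitoquant_sampling_error")
})

test_that("top-k unconnected sums the k largest eligible counts", {
  expect_equal(top_k_unconnected(hpf_grid(matrix(1:16, 4)), 10), sum(7:16))
  expect_equal(top_k_unconnected(hpf_grid(matrix(5L, 4, 4)), 10), 50)
  g <- random_grid(12, 6, 6, 3)
  expect_gte(top_k_unconnected(g, 10), dfs_max_path(g, 10)$count)
})

test_that("MC-only grading applies the 4 and 20 thresholds", {
  expect_equal(grade_from_mc(4), 2L)    # borderline upgrade to grade 2
  expect_equal(grade_from_mc(21), 3L)   # clear grade 3 by count alone
  expect_equal(grade_from_mc(c(0, 3.9, 19.9, 20)), c(1L, 1L, 2L, 3L))
  expect_error(grade_from_mc(-1), class = "mitoquant_parameter_error")
  expect_error(grade_from_mc(5, thresholds = c(20, 4)),
               class = "mitoquant_parameter_error")
  expect_equal(grade_from_mc(5, thresholds = c(6, 10)), 1L)
})

test_that("the domination chain orders the quantifiers on arbitrary fixtures", {
  for (seed in c(2, 13, 44)) {
    pts <- clustered_points(seed, edge = 100)
    rep <- quantify_all(pts, grid_spec(hpf_edge_px = 100),
                        config = run_config(hpf_edge_px = 100, random_reps = 100,
                                            seed = seed))
    s <- glance(rep)
    expect_gte(s$top10_unconnected, s$dfs_mc)
    expect_gte(s$dfs_mc, s$linear_max)
    expect_gte(s$dfs_mc, s$rect_max)
    expect_gte(s$dfs_mc, rep$average_per_10 - 1e-9)
  }
})

test_that("masking never increases any quantifier", {
  pts <- clustered_points(3, edge = 100)
  spec <- grid_spec(hpf_edge_px = 100)
  cfg <- run_config(hpf_edge_px = 100, random_reps = 50, seed = 1)
  base <- glance(quantify_all(pts, spec, NULL, cfg))
  mask <- mask_polygons(list(square_poly(400, 300, 300)))
  masked <- glance(quantify_all(pts, spec, mask, cfg))
  for (col in c("dfs_mc", "linear_max", "rect_max", "top10_unconnected")) {
    expect_lte(masked[[col]], base[[col]])
  }
})

test_that("quantify_all handles the empty slide and the degenerate strip", {
  rep0 <- quantify_all(data.frame(x = double(), y = double()))
  s0 <- glance(rep0)
  expect_equal(s0$dfs_mc, 0)
  expect_equal(s0$top10_unconnected, 0)
  expect_equal(s0$grade_mc_only, 1L)

  pts <- data.frame(x = rep(50 + 0:9 * 100, times = 1:10), y = 50)
  rep1 <- quantify_all(pts, grid_spec(hpf_edge_px = 100),
                       config = run_config(hpf_edge_px = 100, random_reps = 10, seed = 1))
  s1 <- glance(rep1)
  expect_equal(s1$dfs_mc, 55)
  expect_equal(rep1$linear_h$count, 55)
  expect_equal(s1$top10_unconnected, 55)
  expect_equal(rep1$average_per_10, 55)
})

test_that("origin-shift scan reproduces the baseline at (0,0) and its maximum dominates", {
  pts <- clustered_points(17, edge = 100)
  spec <- grid_spec(hpf_edge_px = 100)
  cfg <- run_config(hpf_edge_px = 100, random_reps = 10, seed = 1)
  tab1 <- origin_shift_scan(pts, spec, NULL, list(c(0, 0)), config = cfg)
  expect_equal(nrow(tab1), 1L)
  base <- glance(quantify_all(pts, spec, NULL, cfg))
  expect_equal(tab1$dfs, base$dfs_mc)
  expect_equal(max(tab1$linear_v, tab1$linear_h), base$linear_max)

  offs <- expand.grid(dx = c(0, 25, 50, 75), dy = c(0, 25, 50, 75))
  tab <- origin_shift_scan(pts, spec, NULL, offs, config = cfg)
  expect_equal(nrow(tab), 16L)
  sm <- attr(tab, "scan_max")
  expect_gte(sm[["dfs"]], base$dfs_mc)
  expect_gte(sm[["top10_unconnected"]], base$top10_unconnected)
  expect_error(origin_shift_scan(pts, spec, NULL, list(), config = cfg),
               class = "mitoquant_parameter_error")
})
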