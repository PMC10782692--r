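test_that("clustering groups coincident and chained marks, splits distant ones", {
  # three annotators on the identical pixel
  cl <- cluster_annotations(data.frame(x = 500, y = 500,
                                       annotator = c("a", "b", "c")))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$votes, 3L)
  expect_equal(c(cl$x, cl$y), c(500, 500))

  # 20 um apart at radius 15 um: two candidates (20 um = 80 px at 0.25 um/px)
  cl2 <- cluster_annotations(data.frame(x = c(0, 80), y = 0,
                                        annotator = c("a", "b")))
  expect_equal(nrow(cl2), 2L)
  expect_equal(cl2$votes, c(1L, 1L))

  # chain at 0, 10, 20 um merges by single linkage
  cl3 <- cluster_annotations(data.frame(x = c(0, 40, 80), y = 0,
                                        annotator = c("a", "b", "c")))
  expect_equal(nrow(cl3), 1L)
  expect_equal(cl3$votes, 3L)

  # a double-marking annotator still casts one vote
  cl4 <- cluster_annotations(data.frame(x = c(0, 4, 8), y = 0,
                                        annotator = c("a", "a", "b")))
  expect_equal(cl4$votes, 2L)
  expect_equal(nrow(cl4$members[[1]]), 3L)

  expect_equal(nrow(cluster_annotations(data.frame(x = double(), y = double(),
                                                   annotator = character()))), 0L)
})

test_that("clustering is invariant to annotation row order", {
  set.seed(8)
  ann <- data.frame(x = runif(60, 0, 4000), y = runif(60, 0, 4000),
                    annotator = sample(letters[1:5], 60, replace = TRUE))
  a <- cluster_annotations(ann)
  b <- cluster_annotations(ann[sample(nrow(ann)), ])
  key <- function(d) d[order(d$x, d$y), c("x", "y", "votes")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("majority voting keeps exactly the strict-majority candidates", {
  mk <- function(votes) {
    dplyr::bind_rows(lapply(seq_along(votes), function(i) {
      data.frame(x = i * 1000, y = 0, annotator = paste0("a", seq_len(votes[i])))
    }))
  }
  cl <- cluster_annotations(mk(c(2, 1)))
  kept3 <- majority_vote(cl, 3)
  expect_equal(nrow(kept3), 1L)        # 2 > 1.5 kept, 1 dropped
  expect_equal(kept3$votes, 2L)

  cl5 <- cluster_annotations(mk(c(3, 2)))
  kept5 <- majority_vote(cl5, 5)
  expect_equal(kept5$votes, 3L)        # 3 > 2.5 kept, 2 < 2.5 dropped

  expect_error(majority_vote(cl, 4), class = "mitoquant_parameter_error")
})

test_that("raising the vote threshold never adds kept candidates", {
  set.seed(4)
  ann <- dplyr::bind_rows(lapply(1:9, function(i) {
    sites <- data.frame(x = (1:20) * 500, y = 0)
    sites[runif(20) < 0.5, , drop = FALSE] |> transform(annotator = paste0("r", i))
  }))
  cl <- cluster_annotations(ann)
  kept_by_k <- lapply(c(3, 5, 7, 9), function(k) majority_vote(cl, k)$x)
  for (i in 2:4) expect_true(all(kept_by_k[[i]] %in% kept_by_k[[i - 1]]))
})

test_that("agreement rates are percentages of the reader pool, split by truth status", {
  ann <- dplyr::bind_rows(
    data.frame(x = 100, y = 100, annotator = paste0("r", 1:41)),  # all agree
    data.frame(x = 5000, y = 5000, annotator = c("r1", "r2")),    # 2 of 41
    data.frame(x = 9000, y = 9000, annotator = paste0("r", 1:5))  # 5 of 41, FP
  )
  cl <- cluster_annotations(ann)
  ar <- agreement_rates(cl, 41)
  expect_equal(sort(ar$rate_pct), sort(100 * c(41, 2, 5) / 41), tolerance = 1e-12)
  expect_equal(ar$rate_pct[ar$votes == 2], 100 * 2 / 41)  # ~4.88%

  truth <- data.frame(x = c(100, 5000), y = c(100, 5000))
  ar2 <- agreement_rates(cl, 41, truth = truth)
  expect_setequal(ar2$group[ar2$votes %in% c(41, 2)], "ground_truth")
  expect_equal(ar2$group[ar2$votes == 5], "false_positive")
  # low-agreement false positives are dropped under the votes > 3 rule
  ann3 <- rbind(ann, data.frame(x = 12000, y = 12000, annotator = c("r1", "r2")))
  ar3 <- agreement_rates(cluster_annotations(ann3), 41, truth = truth)
  expect_false(any(ar3$group == "false_positive" & ar3$votes <= 3))
})

test_that("a pool of identical annotators makes every group equal the individual", {
  sites <- data.frame(x = (1:15) * 1000, y = 500)
  ann <- coincident_annotations(sites, paste0("r", 1:9))
  truth <- sites[1:10, ]   # 5 of the marked sites are spurious
  ind <- evaluate_annotators(ann, truth)
  ge <- group_sampling_experiment(ann, truth, sizes = c(3, 5), reps = 5, seed = 2)
  expect_true(all(ge$precision == ind$precision[1]))
  expect_true(all(ge$sensitivity == ind$sensitivity[1]))
})

test_that("group experiment bookkeeping: one row per size and replicate, seeded", {
  rs <- simulate_reader_study(n_truth = 30, n_decoys = 30, n_annotators = 9,
                              extent = c(8000, 8000), seed = 5)
  ge <- group_sampling_experiment(rs$annotations, rs$truth,
                                  sizes = c(3, 5, 7), reps = 4, seed = 1)
  expect_equal(nrow(ge), 12L)
  expect_equal(unname(table(ge$group_size)), rep(4L, 3), ignore_attr = TRUE)
  expect_true(all(ge$tp + ge$fn == nrow(rs$truth)))
  ge2 <- group_sampling_experiment(rs$annotations, rs$truth,
                                   sizes = c(3, 5, 7), reps = 4, seed = 1)
  expect_identical(as.data.frame(ge), as.data.frame(ge2))
  expect_error(group_sampling_experiment(rs$annotations, rs$truth,
                                         sizes = 11, reps = 2),
               class = "mitoquant_parameter_error")
  expect_error(group_sampling_experiment(rs$annotations, rs$truth,
                                         sizes = 4, reps = 2),
               class = "mitoquant_parameter_error")
})
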