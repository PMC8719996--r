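test_that("metrics are exact on identity and anti-identity masks", {
  set.seed(19)
  truth <- matrix(sample(0:1, 64, replace = TRUE), 8, 8)
  same <- seg_metrics(truth, truth, labels = 0:1)
  expect_equal(same$pixel_accuracy, 1)
  expect_true(all(same$dice == 1))
  anti <- seg_metrics(1L - truth, truth, labels = 0:1)
  expect_equal(anti$pixel_accuracy, 0)
  expect_true(all(anti$dice == 0))
  expect_error(seg_metrics(truth, truth[1:4, 1:4]),
               class = "obstruseg_validation_error")
})

test_that("the 4x4 hand case gives accuracy 0.75 and the enumerated Dice", {
  truth <- matrix(c(1, 1, 1, 1,
                    1, 1, 0, 0,
                    0, 0, 0, 0,
                    0, 0, 0, 0), 4, 4, byrow = TRUE)
  pred <- matrix(c(1, 1, 0, 0,
                   1, 1, 0, 0,
                   0, 0, 1, 1,
                   0, 0, 0, 0), 4, 4, byrow = TRUE)
  # by hand: correct = 4 TP + 8 TN = 12 of 16; |P1| = 6, |T1| = 6, TP = 4
  m <- seg_metrics(pred, truth, labels = 0:1)
  expect_equal(m$pixel_accuracy, 0.75)
  expect_equal(m$dice[["1"]], 2 * 4 / (6 + 6))
  expect_equal(sum(m$confusion), 16)
})

test_that("Dice and IoU satisfy their identity on random masks", {
  set.seed(20)
  for (rep in 1:50) {
    truth <- matrix(sample(0:2, 100, replace = TRUE), 10, 10)
    pred <- matrix(sample(0:2, 100, replace = TRUE), 10, 10)
    m <- seg_metrics(pred, truth, labels = 0:2)
    expect_equal(m$dice, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
  }
})

test_that("recognition rates count per category and ignore order", {
  all_right <- recognition_rate(c("a", "b", "b"), c("a", "b", "b"))
  expect_true(all(all_right$rates == 1))
  r <- recognition_rate(c("A", "B", "B", "B"), c("A", "A", "B", "B"))
  expect_equal(r$rates[["A"]], 0.5)
  expect_equal(r$rates[["B"]], 1)
  perm <- sample(4)
  r2 <- recognition_rate(c("A", "B", "B", "B")[perm], c("A", "A", "B", "B")[perm])
  expect_equal(r2$rates, r$rates)
  # an empty category is reported missing, never silently zero
  r3 <- recognition_rate(c("A", "A"), c("A", "A"), classes = c("A", "C"))
  expect_true(is.na(r3$rates[["C"]]))
  expect_equal(r3$macro, 1)
})

test_that("stratified folds are disjoint, exhaustive, and balanced", {
  y <- rep(0:2, c(10, 8, 6))
  fold <- obstruseg:::stratified_folds(y, 3, seed = 21)
  expect_equal(sort(unique(fold)), 1:3)
  expect_length(fold, length(y))
  for (cl in 0:2)
    expect_true(max(table(fold[y == cl])) - min(table(fold[y == cl])) <= 1)
  expect_error(obstruseg:::stratified_folds(rep(0:1, c(10, 2)), 3),
               class = "obstruseg_validation_error")
})

separable_block_set <- function() {
  # three tight, well-separated clusters in 6-D feature space
  set.seed(22)
  X <- rbind(matrix(rnorm(40 * 6, 0, 0.05), 40, 6),
             sweep(matrix(rnorm(40 * 6, 0, 0.05), 40, 6), 2, c(2, 0, 0, 0, 0, 0), "+"),
             sweep(matrix(rnorm(40 * 6, 0, 0.05), 40, 6), 2, c(0, 2, 0, 0, 0, 0), "+"))
  list(X = X, y = rep(0:2, each = 40))
}

test_that("hidden-layer sweep reaches accuracy 1 on a separable set", {
  ds <- separable_block_set()
  res <- hl_sweep(ds, hidden_counts = 2, k_folds = 2,
                  ga_cfg = list(population_size = 10L, max_generations = 5L),
                  train_cfg = list(max_epochs = 200L), seed = 1)
  expect_equal(res$mean_accuracy, 1)
  res2 <- hl_sweep(ds, hidden_counts = 2, k_folds = 2,
                   ga_cfg = list(population_size = 10L, max_generations = 5L),
                   train_cfg = list(max_epochs = 200L), seed = 1)
  expect_identical(res, res2)  # deterministic per seed
  expect_equal(res$n_hidden, 2)
})

test_that("block parameter sweep reports a row per valid setting", {
  pairs <- tiny_phantom_pairs(1, size = 64, noise_sd = 0.02)
  cfg <- tiny_cfg()
  warns <- testthat::capture_warnings(
    res <- block_param_sweep(pairs[1:2], pairs[3:4], block_sizes = c(32L, 96L),
                             overlap_steps = c(16L, 32L), cfg = cfg, seed = 2))
  expect_true(all(grepl("skipping", warns)) && length(warns) == 2)
  expect_equal(nrow(res), 2L)  # the two valid (32, s) pairs
  g <- extract_blocks(pairs[[3]]$image, 32, 16)
  expect_equal(res$n_blocks[res$overlap_step == 16], nrow(g$origins))
  expect_true(all(res$seconds >= 0))
})
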