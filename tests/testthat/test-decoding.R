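# Decoding pipeline: period windows, label bookkeeping, undersampling,
# sparse one-vs-rest classifiers, cross-validation and the permutation test.

toy_dataset <- function(n_per_class = 12, n_features = 20, classes = c(1, 2, 4),
                        sep = 6, sd = 0.5, n_sessions = 2, seed = 1,
                        n_games = 4) {
  # well-separated Gaussian blobs, identical across the 9 periods
  set.seed(seed)
  n <- n_per_class * length(classes)
  centers <- matrix(rnorm(length(classes) * n_features), length(classes))
  centers <- centers / sqrt(rowSums(centers^2)) * sep
  lab <- rep(classes, each = n_per_class)
  X <- centers[match(lab, classes), ] + matrix(rnorm(n * n_features, 0, sd), n)
  arr <- array(0, dim = c(n, 9, n_features))
  for (t in 1:9) arr[, t, ] <- X
  # sessions and games cycle within each class so folds stay balanced
  session0 <- rep_len(seq_len(n_sessions), n)
  game0 <- rep_len(seq_len(n_games), n)
  ord <- sample.int(n)
  structure(list(
    patterns = arr[ord, , , drop = FALSE],
    labels = data.frame(trial = 1:n, scene = lab[ord],
                        conf = rep_len(c(0L, 1L), n),
                        state_conf = rep_len(c(0L, 1L), n),
                        correct = TRUE,
                        session = session0[ord],
                        game = game0[ord],
                        trial_index = 1:n),
    subject_id = "toy", spec = NULL), class = "pattern_dataset")
}

test_that("period features average the four scans starting at t", {
  scans <- matrix(rep(1:12, 3), nrow = 12)
  scans[, 2] <- (1:12) * 10
  expect_equal(period_features(scans, 0), c(mean(1:4), mean(1:4) * 10, mean(1:4)))
  expect_equal(period_features(scans, 8), c(mean(9:12), mean(9:12) * 10, mean(9:12)))
  # constant series: the constant
  const <- matrix(5, nrow = 6, ncol = 4)
  expect_equal(period_features(const, 2), rep(5, 4))
  expect_error(period_features(const, 3), "period 3")
})

test_that("the rarest scene label is excluded, ties to the lowest label", {
  ds <- toy_dataset(classes = c(1, 2, 4))
  ds$labels$scene[ds$labels$scene == 2][1:5] <- 1  # make 2 the rarest
  res <- exclude_rare_label(ds)
  expect_identical(res$excluded_label, 2L)
  expect_false(2 %in% res$dataset$labels$scene)
  expect_identical(nrow(res$dataset$labels), dim(res$dataset$patterns)[1])
  # seven labels in, six out
  ds7 <- toy_dataset(n_per_class = 4, classes = 1:7)
  ds7$labels$scene[ds7$labels$scene == 3][1] <- 4  # 3 becomes rarest
  res7 <- exclude_rare_label(ds7)
  expect_identical(length(unique(res7$dataset$labels$scene)), 6L)
  # exact tie between two labels: the lower one goes
  ds_tie <- toy_dataset(n_per_class = 10, classes = c(2, 5, 6))
  expect_identical(exclude_rare_label(ds_tie)$excluded_label, 2L)
})

test_that("undersampling balances classes at the minority count", {
  rng <- mazenav:::make_rng(3)
  labels <- rep(c("A", "B", "C"), c(5, 3, 7))
  idx <- undersample(labels, rng)
  expect_true(all(table(labels[idx]) == 3L))
  expect_identical(length(idx), 9L)
  expect_false(anyDuplicated(idx) > 0)
  # already balanced: a full permutation-invariant subset
  lab2 <- rep(c("A", "B"), each = 4)
  expect_identical(sort(undersample(lab2, rng)), 1:8)
})

test_that("sparse one-vs-rest classifiers separate a toy problem and select few features", {
  ds <- toy_dataset(n_per_class = 15, n_features = 60, sd = 0.3, seed = 5)
  X <- ds$patterns[, 1, ]
  y <- ds$labels$scene
  rng <- mazenav:::make_rng(7)
  fit <- train_ovr_sparse(X, y, rng = rng)
  expect_identical(sort(unique(predict(fit, X))), sort(unique(y)))
  expect_equal(mean(predict(fit, X) == y), 1)
  expect_lt(fit$n_selected_features, 60)
  # binary target: a single classifier
  yb <- ds$labels$conf
  Xb <- X + outer(yb, rep(1, ncol(X)))  # inject signal
  fitb <- train_ovr_sparse(Xb, yb, rng = rng)
  expect_length(fitb$fits, 1L)
  expect_gt(mean(predict(fitb, Xb) == yb), 0.9)
  # all-constant features are rejected
  expect_error(train_ovr_sparse(matrix(1, 20, 5), rep(c(0, 1), 10), rng = rng),
               "degenerate")
})

test_that("cross-validation respects folds and never touches the test set", {
  ds <- toy_dataset(n_per_class = 16, n_sessions = 4, sd = 0.3, seed = 9)
  cfg <- decoding_config(target = "scene", periods = 3, cv = "LOSO",
                         n_undersample_repeats = 2, rng_seed = 5)
  res <- cross_validate(ds, cfg)
  expect_false(res$excluded)
  expect_identical(nrow(res$folds), 4L)  # one fold per session
  expect_setequal(res$folds$fold, 1:4)
  # perfectly separable data decodes perfectly
  expect_equal(res$period_accuracy$accuracy, 1)
  # deterministic under the config seed
  res2 <- cross_validate(ds, cfg)
  expect_identical(res$folds, res2$folds)
})

test_that("subjects violating the minimum-training-samples rule are excluded with reasons", {
  ds <- toy_dataset(n_per_class = 6, n_sessions = 2, n_games = 3, seed = 11)
  # leave only 2 samples of class 4 overall: any training fold has < 3
  keep <- c(which(ds$labels$scene != 4), which(ds$labels$scene == 4)[1:2])
  ds$patterns <- ds$patterns[keep, , , drop = FALSE]
  ds$labels <- ds$labels[keep, ]
  cfg <- decoding_config(target = "scene", periods = 1,
                         n_undersample_repeats = 1, cv = "LOGO")
  res <- conditional_decode(ds, "correct", cfg)
  expect_true(res$excluded)
  expect_match(res$reason, "fewer than 3 training samples")
  # an empty condition subset is excluded too
  ds2 <- toy_dataset(seed = 12)
  ds2$labels$correct <- TRUE
  res2 <- conditional_decode(ds2, "incorrect", cfg)
  expect_true(res2$excluded)
})

test_that("a condition filter over all trials equals plain leave-one-game-out decoding", {
  ds <- toy_dataset(n_per_class = 12, n_games = 4, sd = 0.4, seed = 13)
  ds$labels$correct <- TRUE
  cfg <- decoding_config(target = "scene", periods = 2,
                         n_undersample_repeats = 3, cv = "LOGO", rng_seed = 21)
  a <- conditional_decode(ds, "correct", cfg)
  b <- cross_validate(ds, cfg)
  expect_equal(a$period_accuracy, b$period_accuracy)
})

test_that("condition comparisons are one-sided rank-sum with sample guards", {
  mk <- function(acc) structure(list(
    subject_id = "x", excluded = FALSE,
    period_accuracy = data.frame(period = 6, accuracy = acc)),
    class = "decoding_result")
  a <- lapply(c(0.9, 0.85, 0.8, 0.95), mk)
  b <- lapply(c(0.3, 0.25, 0.35, 0.2), mk)
  res <- compare_conditions(a, b, 6)
  expect_true(res$testable)
  expect_lt(res$p, 0.05)
  same <- compare_conditions(a, a, 6)
  expect_gt(same$p, 0.4)
  short <- compare_conditions(a[1:2], b, 6)
  expect_false(short$testable)
})

test_that("the permutation pool holds n_sbj + 1 entries including the original", {
  ds1 <- toy_dataset(n_per_class = 8, n_features = 10, n_sessions = 2,
                     sd = 0.5, seed = 17)
  ds2 <- toy_dataset(n_per_class = 8, n_features = 10, n_sessions = 2,
                     sd = 0.5, seed = 18)
  cfg <- decoding_config(target = "scene", periods = 4,
                         n_undersample_repeats = 1, cv = "LOSO",
                         lambda = 0.05, rng_seed = 2)
  pt <- permutation_test_two_step(list(ds1, ds2), cfg, n_sbj = 3,
                                  n_group = 20, rng_seed = 4)
  expect_length(pt$pools, 2L)
  expect_length(pt$pools[[1]], 4L)
  expect_length(pt$null, 20L)
  # strong signal: originals sit above the permutation null
  expect_lt(pt$p, 0.05)
  expect_identical(pt$original,
                   vapply(pt$pools, `[`, numeric(1), 1L))
})
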