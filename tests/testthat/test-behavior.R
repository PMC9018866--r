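# Behavioral statistics: exclusion z-test, confidence effects, trial-index
# trends, streaks, normalized reaction times, confidence agreement.

fake_log <- function(subject_id, pred_df) {
  # minimal behavior_log wrapper around a prediction-trial table
  pred_df$trial_type <- "prediction"
  if (is.null(pred_df$missed)) pred_df$missed <- FALSE
  behavior_log(pred_df, subject_id)
}

test_that("the exclusion z-test matches its closed form", {
  # accuracy exactly at chance: z = 0, p = 0.5, excluded at any n
  at_chance <- fake_log("chance", data.frame(
    game = 1, trial_index = 1:80, correct = rep(c(TRUE, FALSE, FALSE, FALSE), 20),
    confidence_report = 2, session = 1, rt_scene_choice = 1))
  res <- exclude_subjects(list(at_chance))
  expect_equal(res$z, 0)
  expect_equal(res$p, 0.5)
  expect_false(res$kept)
  # 120/200 correct: z = (0.6 - 0.25) / sqrt(0.25 * 0.75 / 200)
  good <- fake_log("good", data.frame(
    game = 1, trial_index = 1:200, correct = rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), 40),
    confidence_report = 2, session = 1, rt_scene_choice = 1))
  res2 <- exclude_subjects(list(good))
  expect_equal(res2$z, (0.6 - 0.25) / sqrt(0.25 * 0.75 / 200), tolerance = 1e-12)
  expect_equal(res2$z, 11.43, tolerance = 1e-3)
  expect_true(res2$kept)
  # missed trials are dropped before testing
  with_miss <- fake_log("miss", data.frame(
    game = 1, trial_index = 1:100,
    correct = c(rep(TRUE, 50), rep(FALSE, 50)),
    missed = c(rep(FALSE, 80), rep(TRUE, 20)),
    confidence_report = 2, session = 1, rt_scene_choice = 1))
  expect_identical(exclude_subjects(list(with_miss))$n, 80L)
})

test_that("a random guesser is excluded in almost all replicates", {
  set.seed(101)
  excluded <- vapply(1:300, function(i) {
    l <- fake_log("g", data.frame(
      game = 1, trial_index = 1:200, correct = runif(200) < 0.25,
      confidence_report = 2, session = 1, rt_scene_choice = 1))
    !exclude_subjects(list(l))$kept
  }, logical(1))
  expect_gte(mean(excluded), 0.97)
})

test_that("accuracy by confidence handles degenerate subjects and null effects", {
  all_high <- fake_log("ah", data.frame(
    game = 1, trial_index = 1:40, correct = TRUE, confidence_report = 4,
    session = 1, rt_scene_choice = 1))
  both <- fake_log("ok", data.frame(
    game = 1, trial_index = 1:40, correct = rep(c(TRUE, FALSE), 20),
    confidence_report = rep(c(4, 1), each = 20), session = 1,
    rt_scene_choice = 1))
  res <- accuracy_by_confidence(list(all_high, both))
  expect_identical(res$dropped, "ah")
  expect_identical(res$n_tested, 1L)
  # identical accuracies on both sides across subjects: no effect
  flat <- lapply(1:6, function(i) fake_log(paste0("s", i), data.frame(
    game = 1, trial_index = 1:40, correct = rep(c(TRUE, FALSE), 20),
    confidence_report = rep(c(1, 4), 20), session = 1, rt_scene_choice = 1)))
  res2 <- accuracy_by_confidence(flat)
  expect_gte(res2$p, 0.45)
})

test_that("trial-index trends recover exact and degenerate correlations", {
  inc <- fake_log("inc", data.frame(
    game = rep(1:8, each = 5), trial_index = sequence(rep(5, 8)),
    correct = TRUE, confidence_report = rep(0:4, 8) / 2 + 1,
    session = 1, rt_scene_choice = 1))
  # strictly increasing measure: r = 1
  inc$trials$confidence_report <- rep(1:5, 8)
  tr <- trend_vs_trial_index(list(inc), "confidence")
  expect_equal(tr$r, 1)
  expect_false(tr$undefined)
  # constant measure: undefined, flagged
  tr2 <- trend_vs_trial_index(list(inc), "accuracy")
  expect_true(tr2$undefined)
  expect_true(is.na(tr2$r))
})

test_that("streak runs reset at game boundaries and polarity changes", {
  # hand-computed fixture: games with prediction outcomes C,C,I,C | I,I,C
  log <- fake_log("st", data.frame(
    game = rep(1:2, c(4, 3)), trial_index = c(1:4, 1:3),
    correct = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
    confidence_report = 2, session = 1, rt_scene_choice = 1))
  st <- streak_analysis(list(log))
  runs <- st$trial_runs
  expect_identical(runs$prev_correct_run, c(0L, 1L, 2L, 0L, 0L, 0L, 0L))
  expect_identical(runs$prev_incorrect_run, c(0L, 0L, 0L, 1L, 0L, 1L, 2L))
})

test_that("reaction-time normalization is session-wise with variance guards", {
  log <- fake_log("rt", data.frame(
    game = 1, trial_index = 1:60,
    correct = rep(c(TRUE, FALSE), 30),
    confidence_report = rep(c(4, 1), each = 30),
    session = rep(1:2, each = 30),
    rt_scene_choice = c(rnorm(30, 1.5, 0.3), rnorm(30, 2.5, 0.5))))
  res <- rt_zscore_and_summarize(list(log))
  for (s in 1:2) {
    z <- res$trials$rt_z[res$trials$session == s]
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
  # constant-RT session is dropped with a warning
  log2 <- fake_log("rt2", data.frame(
    game = 1, trial_index = 1:20, correct = TRUE, confidence_report = 2,
    session = rep(1:2, each = 10),
    rt_scene_choice = c(rep(1.4, 10), rnorm(10, 2, 0.2))))
  expect_warning(res2 <- rt_zscore_and_summarize(list(log2)), "dropped")
  expect_true(all(res2$trials$session == 2))
})

test_that("confidence agreement is exact at the aligned extremes", {
  m <- fixture_maze_5()
  log <- quick_log(n_games = 2, seed = 29, m = m)
  tr <- filter_log(log, m, default_theta())
  p <- log$trials[log$trials$trial_type == "prediction" & !log$trials$missed, ]
  # a trace that mirrors the reports exactly -> 100%
  tr_perfect <- tr
  key <- match(paste(p$game, p$trial_index),
               paste(tr$predictions$game, tr$predictions$trial_index))
  tr_perfect$predictions$c_hat[key] <- as.integer(p$confidence_report >= 3)
  expect_equal(confidence_agreement(log, tr_perfect), 100)
  tr_anti <- tr
  tr_anti$predictions$c_hat[key] <- 1L - as.integer(p$confidence_report >= 3)
  expect_equal(confidence_agreement(log, tr_anti), 0)
  # misaligned trace -> alignment error
  tr_bad <- tr
  tr_bad$predictions <- tr_bad$predictions[-1, ]
  expect_error(confidence_agreement(log, tr_bad), "aligned")
})
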