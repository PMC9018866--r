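# Behavioral analyses of prediction-trial performance: subject exclusion,
# accuracy by confidence, trends over prediction-trial index, streaks,
# normalized reaction times, and model-vs-reported confidence agreement.
# All group comparisons are one-sided rank tests, as appropriate for paired
# (signed-rank) or independent (rank-sum) two-group designs; with single
# two-group comparisons no multiplicity correction applies.

pred_trials <- function(log, drop_missed = TRUE) {
  tr <- if (inherits(log, "behavior_log")) log$trials else log
  p <- tr[tr$trial_type == "prediction", , drop = FALSE]
  if (drop_missed) p <- p[!p$missed, , drop = FALSE]
  p
}

# prediction-trial index within each game (1-based)
with_pred_index <- function(p) {
  p <- p[order(p$game, p$trial_index), ]
  p$pred_index <- stats::ave(seq_len(nrow(p)), p$game, FUN = seq_along)
  p
}

#' Exclude subjects whose prediction accuracy is not above chance
#'
#' One-sided one-proportion z-test of each subject's scene prediction
#' accuracy against the four-option chance level; a subject is excluded when
#' p >= `alpha_level`. Missed prediction trials are dropped first.
#'
#' @param logs list of `behavior_log`.
#' @param alpha_level significance threshold (default 0.01).
#' @param chance chance accuracy (0.25 with four options).
#' @return data.frame per subject: n trials, accuracy, z, p, `kept`.
#' @export
exclude_subjects <- function(logs, alpha_level = 0.01, chance = 0.25) {
  rows <- lapply(logs, function(log) {
    p <- pred_trials(log)
    if (!nrow(p))
      return(data.frame(subject_id = log$subject_id, n = 0L, accuracy = NA,
                        z = NA, p = NA, kept = FALSE, valid = FALSE))
    acc <- mean(p$correct)
    z <- (acc - chance) / sqrt(chance * (1 - chance) / nrow(p))
    pval <- stats::pnorm(z, lower.tail = FALSE)
    data.frame(subject_id = log$subject_id, n = nrow(p), accuracy = acc,
               z = z, p = pval, kept = pval < alpha_level, valid = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prediction accuracy at high versus low confidence
#'
#' Per-subject accuracies for high (levels 3--4) and low (1--2) reported
#' confidence, compared at the cohort level with a one-sided Wilcoxon
#' signed-rank test (high > low). Subjects with all trials on one side are
#' dropped from the paired test and reported.
#'
#' @param logs list of `behavior_log`.
#' @return list: `per_subject` (acc_high, acc_low, tested), `p` (one-sided
#'   signed-rank), `n_tested`, `dropped` subject ids.
#' @export
accuracy_by_confidence <- function(logs) {
  per <- do.call(rbind, lapply(logs, function(log) {
    p <- pred_trials(log)
    hi <- p$correct[p$confidence_report >= 3L]
    lo <- p$correct[p$confidence_report <= 2L]
    data.frame(subject_id = log$subject_id,
               acc_high = if (length(hi)) mean(hi) else NA_real_,
               acc_low = if (length(lo)) mean(lo) else NA_real_,
               n_high = length(hi), n_low = length(lo))
  }))
  per$tested <- !is.na(per$acc_high) & !is.na(per$acc_low)
  pv <- if (sum(per$tested) >= 1L)
    stats::wilcox.test(per$acc_high[per$tested], per$acc_low[per$tested],
                       paired = TRUE, alternative = "greater",
                       exact = FALSE)$p.value
  else NA_real_
  rownames(per) <- NULL
  list(per_subject = per, p = pv, n_tested = sum(per$tested),
       dropped = per$subject_id[!per$tested])
}

#' Trend of a measure over the prediction-trial index
#'
#' Correlates a per-trial measure (accuracy, reported confidence level, or
#' the fraction of trials the model assigns high state confidence) with the
#' prediction-trial number within a game, over per-(subject, index) means.
#' Indices above the `cap_quantile` quantile of per-game prediction counts
#' are pooled out (sparse tail).
#'
#' @param logs list of `behavior_log`.
#' @param measure `"accuracy"`, `"confidence"` or
#'   `"high_state_conf_fraction"`.
#' @param traces for the model measure, a list (parallel to `logs`) of
#'   [filter_log()] results supplying `c_hat` per prediction trial.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param unit `"subject_index_mean"` (default) correlates per-(subject,
#'   index) means; `"pooled"` correlates raw trials.
#' @param cap_quantile quantile of per-game prediction counts above which
#'   indices are dropped.
#' @return list: `r`, `p`, `points` (the correlated table), `undefined`
#'   (`TRUE` when the measure is constant so r does not exist).
#' @export
trend_vs_trial_index <- function(logs, measure = c("accuracy", "confidence",
                                                   "high_state_conf_fraction"),
                                 traces = NULL,
                                 method = c("pearson", "spearman"),
                                 unit = c("subject_index_mean", "pooled"),
                                 cap_quantile = 0.95) {
  measure <- match.arg(measure); method <- match.arg(method)
  unit <- match.arg(unit)
  rows <- list()
  for (i in seq_along(logs)) {
    log <- logs[[i]]
    p <- with_pred_index(pred_trials(log))
    val <- switch(measure,
      accuracy = as.numeric(p$correct),
      confidence = as.numeric(p$confidence_report),
      high_state_conf_fraction = {
        if (is.null(traces)) stop("traces required for the model measure")
        tr <- traces[[i]]$predictions
        key <- paste(p$game, p$trial_index)
        as.numeric(tr$c_hat[match(key, paste(tr$game, tr$trial_index))])
      })
    rows[[i]] <- data.frame(subject_id = log$subject_id, game = p$game,
                            pred_index = p$pred_index, value = val)
  }
  d <- do.call(rbind, rows)
  d <- d[!is.na(d$value), ]
  counts <- tapply(d$pred_index, paste(d$subject_id, d$game), max)
  cap <- stats::quantile(counts, cap_quantile, names = FALSE, type = 1)
  d <- d[d$pred_index <= cap, ]
  pts <- if (unit == "pooled") d[, c("pred_index", "value")]
  else {
    agg <- stats::aggregate(value ~ subject_id + pred_index, d, mean)
    agg[, c("pred_index", "value")]
  }
  if (length(unique(pts$value)) < 2L || length(unique(pts$pred_index)) < 2L)
    return(list(r = NA_real_, p = NA_real_, points = pts, undefined = TRUE))
  ct <- stats::cor.test(pts$pred_index, pts$value, method = method,
                        exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, points = pts,
       undefined = FALSE)
}

#' Run lengths of preceding correct / incorrect predictions
#'
#' For every prediction trial, the length of the immediately preceding run of
#' correct (respectively incorrect) predictions within the same game; runs
#' reset at game boundaries and at polarity changes, and the trial ending a
#' run is not part of its own predictor run. Accuracy is then correlated with
#' run length over per-(subject, length) means.
#'
#' @param logs list of `behavior_log`.
#' @return list: `trial_runs` (per-trial run lengths), `curve_correct` /
#'   `curve_incorrect` (per-length mean accuracies), `r_correct`,
#'   `p_correct`, `r_incorrect`, `p_incorrect`.
#' @export
streak_analysis <- function(logs) {
  run_rows <- list()
  for (log in logs) {
    p <- with_pred_index(pred_trials(log))
    for (g in unique(p$game)) {
      corr <- p$correct[p$game == g]
      nc <- length(corr)
      run_c <- integer(nc); run_i <- integer(nc)
      for (j in seq_len(nc)) {
        if (j == 1L) { run_c[j] <- 0L; run_i[j] <- 0L }
        else {
          run_c[j] <- if (corr[j - 1L]) run_c[j - 1L] + 1L else 0L
          run_i[j] <- if (!corr[j - 1L]) run_i[j - 1L] + 1L else 0L
        }
      }
      run_rows[[length(run_rows) + 1L]] <- data.frame(
        subject_id = log$subject_id, game = g, pred_index = seq_len(nc),
        correct = corr, prev_correct_run = run_c, prev_incorrect_run = run_i)
    }
  }
  d <- do.call(rbind, run_rows)
  curve <- function(runvar) {
    tmp <- data.frame(subject_id = d$subject_id, run_length = d[[runvar]],
                      correct = as.numeric(d$correct))
    stats::aggregate(correct ~ subject_id + run_length, tmp, mean)
  }
  corr_of <- function(agg) {
    if (length(unique(agg$run_length)) < 2L || length(unique(agg$correct)) < 2L)
      return(list(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(agg$run_length, agg$correct, exact = FALSE)
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  cc <- curve("prev_correct_run"); ci <- curve("prev_incorrect_run")
  rc <- corr_of(cc); ri <- corr_of(ci)
  list(trial_runs = d, curve_correct = cc, curve_incorrect = ci,
       r_correct = rc$r, p_correct = rc$p,
       r_incorrect = ri$r, p_incorrect = ri$p)
}

#' Session-normalized reaction times by confidence and correctness
#'
#' Scene-choice reaction times are z-scored within each (subject, session);
#' sessions with fewer than two usable RTs or zero variance are dropped with
#' a warning. Medians are reported by confidence side and correctness, with
#' cohort-level one-sided Wilcoxon rank-sum comparisons (high < low
#' confidence; correct < incorrect).
#'
#' @param logs list of `behavior_log`.
#' @return list: `trials` (with `rt_z`), `medians`, `p_conf` and `p_correct`
#'   (one-sided rank-sum), `dropped_sessions`.
#' @export
rt_zscore_and_summarize <- function(logs) {
  rows <- list(); dropped <- list()
  for (log in logs) {
    p <- pred_trials(log)
    p <- p[!is.na(p$rt_scene_choice), , drop = FALSE]
    for (sess in unique(p$session)) {
      i <- p$session == sess
      rt <- p$rt_scene_choice[i]
      if (length(rt) < 2L || stats::sd(rt) == 0) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          subject_id = log$subject_id, session = sess, n = length(rt))
        next
      }
      q <- p[i, , drop = FALSE]
      q$rt_z <- (rt - mean(rt)) / stats::sd(rt)
      rows[[length(rows) + 1L]] <- q
    }
  }
  if (length(dropped))
    warning(length(dropped), " session(s) dropped from RT normalization")
  d <- do.call(rbind, rows)
  d$conf_side <- ifelse(d$confidence_report >= 3L, "high", "low")
  med <- stats::aggregate(rt_z ~ conf_side + correct, d, stats::median)
  one_sided_less <- function(x, y) {
    if (!length(x) || !length(y)) return(NA_real_)
    stats::wilcox.test(x, y, alternative = "less", exact = FALSE)$p.value
  }
  p_conf <- one_sided_less(d$rt_z[d$conf_side == "high"],
                           d$rt_z[d$conf_side == "low"])
  p_corr <- one_sided_less(d$rt_z[d$correct], d$rt_z[!d$correct])
  list(trials = d, medians = med, p_conf = p_conf, p_correct = p_corr,
       dropped_sessions = if (length(dropped)) do.call(rbind, dropped)
                          else NULL)
}

#' Agreement between model state confidence and reported confidence
#'
#' Fraction of (non-missed) prediction trials on which the model's binary
#' state-confidence estimate matches the reported side (high = levels 3--4).
#'
#' @param log a `behavior_log`.
#' @param trace the [filter_log()] result for the same log.
#' @return percent agreement (0--100).
#' @export
confidence_agreement <- function(log, trace) {
  p <- pred_trials(log)
  tr <- trace$predictions
  key <- paste(p$game, p$trial_index)
  tkey <- paste(tr$game, tr$trial_index)
  idx <- match(key, tkey)
  if (anyNA(idx)) stop("trace is not aligned with the log's prediction trials")
  reported_high <- p$confidence_report >= 3L
  100 * mean(tr$c_hat[idx] == as.integer(reported_high))
}
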