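# Whole-log filtering: runs the incremental Bayesian filter over a behavior
# log, game by game, producing the model-evidence factors for every action
# trial and the model read-outs (state confidence, MAP state, predicted scene
# distribution) at every prediction trial.

# Extract per-game action/prediction structure from a trials data.frame.
game_sequences <- function(trials) {
  lapply(split(trials, trials$game), function(df) {
    df <- df[order(df$trial_index), ]
    act <- df[df$trial_type == "action", ]
    # index (within the action sequence) of the action preceding each
    # prediction trial, plus the true outcome scene revealed by its feedback
    pred <- df[df$trial_type == "prediction", ]
    n_act_before <- vapply(pred$trial_index, function(ti)
      sum(act$trial_index < ti), integer(1))
    list(game = df$game[1L], session = df$session[1L],
         actions = act$action,
         actions_idx = match(act$action, ACTIONS) - 1L,
         scene_labels = as.integer(act$observed_scene_label),
         pred_after = n_act_before,
         pred_trial_index = pred$trial_index,
         pred_outcome_labels = pred$true_next_scene_label)
  })
}

#' Filter a behavior log with the behavioral model
#'
#' Runs the belief filter over every game of a log and returns the filter
#' trace: one row per action trial with the predictive action probability
#' (the model-evidence factor) and, for prediction trials, the model's binary
#' state-confidence estimate, MAP state, and predictive scene distribution.
#'
#' @param log a `behavior_log` (or a trials data.frame).
#' @param m the `maze` the log was recorded in.
#' @param params a `model_params`.
#' @param variant `"switching"`, `"forward_only"` or `"efficient_only"`.
#' @param engine `"cpp"` (compiled whole-game filter; default) or `"r"` (the
#'   reference implementation built on [step_filter()]); both produce
#'   identical traces.
#' @param visited_reset,action_backtrack_resamples,prune,eps see
#'   [step_filter()].
#' @return list with `actions` (data.frame: game, step, action,
#'   predictive_prob, log_lik), `predictions` (data.frame: game, trial_index,
#'   c_hat, p_state_conf_high, map_row, map_col, map_ori,
#'   pred_scene_label, model_option_label with the per-label predictive
#'   distribution in columns p0..p7), `nle` (the summed negative log
#'   evidence) and `zero_guard_count`.
#' @export
filter_log <- function(log, m, params, variant = "switching",
                       engine = c("cpp", "r"),
                       visited_reset = "window",
                       action_backtrack_resamples = FALSE,
                       prune = 1e-8, eps = 1e-10) {
  engine <- match.arg(engine)
  trials <- if (inherits(log, "behavior_log")) log$trials else log
  seqs <- game_sequences(trials)
  act_rows <- list(); pred_rows <- list(); nle <- 0; zg <- 0L
  for (gs in seqs) {
    res <- if (engine == "cpp") filter_game_cpp(gs, m, params, variant,
                                                visited_reset,
                                                action_backtrack_resamples,
                                                prune, eps)
           else filter_game_r(gs, m, params, variant, visited_reset,
                              action_backtrack_resamples, prune, eps)
    nle <- nle - sum(log(res$pred_probs))
    zg <- zg + res$zero_guard_count
    act_rows[[length(act_rows) + 1L]] <- data.frame(
      game = gs$game, step = seq_along(gs$actions), action = gs$actions,
      predictive_prob = res$pred_probs, log_lik = log(res$pred_probs))
    if (length(gs$pred_after)) {
      pd <- res$pred_readouts
      pd$game <- gs$game
      pd$trial_index <- gs$pred_trial_index
      # model's choice among the four displayed options: option with the
      # highest predictive scene probability (ties -> lowest label)
      pred_rows[[length(pred_rows) + 1L]] <- pd
    }
  }
  predictions <- if (length(pred_rows)) do.call(rbind, pred_rows) else NULL
  if (!is.null(predictions)) {
    opts <- trials[trials$trial_type == "prediction",
                   c("game", "trial_index", "opt1", "opt2", "opt3", "opt4")]
    predictions <- merge(predictions, opts, by = c("game", "trial_index"),
                         sort = FALSE)
    pmat <- as.matrix(predictions[, paste0("p", 0:7)])
    predictions$model_option_label <- vapply(seq_len(nrow(predictions)),
      function(i) {
        o <- sort(unlist(predictions[i, c("opt1", "opt2", "opt3", "opt4")]))
        o[which.max(pmat[i, o + 1L])]
      }, numeric(1))
    predictions <- predictions[order(predictions$game,
                                     predictions$trial_index), ]
    rownames(predictions) <- NULL
  }
  list(actions = do.call(rbind, act_rows), predictions = predictions,
       nle = nle, zero_guard_count = zg)
}

# Reference R implementation of a whole-game filter (shared output contract
# with the compiled path).
filter_game_r <- function(gs, m, params, variant, visited_reset,
                          action_backtrack_resamples, prune, eps) {
  K <- length(gs$actions)
  pred_probs <- numeric(K); zg <- 0L
  readouts <- list()
  scenes_hist <- list(); actions_hist <- character(0)
  B <- NULL
  emit_readout <- function(B, a) {
    psd <- predict_scene_dist(B, a, m)
    ms <- map_state(B)
    conf <- vapply(B$hypotheses, `[[`, integer(1), "conf")
    data.frame(c_hat = estimate_state_confidence(B),
               p_state_conf_high = sum(belief_weights(B)[conf == 1L]),
               map_row = ms$row, map_col = ms$col, map_ori = ms$orientation,
               pred_scene_label = psd$label,
               as.list(stats::setNames(psd$dist, paste0("p", 0:7))),
               stringsAsFactors = FALSE)
  }
  for (k in seq_len(K)) {
    sc <- label_to_scene(gs$scene_labels[k])
    if (k == 1L) {
      B <- init_belief(m, sc)
      scenes_hist <- list(sc)
    }
    a <- gs$actions[k]
    if (k %in% gs$pred_after)
      readouts[[length(readouts) + 1L]] <- emit_readout(B, a)
    # outcome scene: next action trial's observation, or (for the game's last
    # action) the scene revealed by the final prediction trial's feedback
    out_label <- if (k < K) gs$scene_labels[k + 1L]
                 else if (length(gs$pred_outcome_labels))
                   gs$pred_outcome_labels[length(gs$pred_outcome_labels)]
                 else NA_integer_
    if (is.na(out_label)) {   # truncated log: no outcome scene for the last
      ph1 <- condition_on_action(B, a, m, params, variant, eps)
      pred_probs[k] <- ph1$predictive_prob
      zg <- zg + as.integer(ph1$zero_guard)
      next
    }
    out_sc <- label_to_scene(out_label)
    nw <- min(params$n_history - 1L, length(actions_hist))
    idx <- seq.int(length(actions_hist) - nw + 1L, length.out = nw)
    history <- list(
      scenes = c(scenes_hist[c(idx, length(scenes_hist))], list(out_sc)),
      actions = c(actions_hist[idx], a))
    st <- step_filter(B, a, out_sc, m, params, history = history,
                      variant = variant, visited_reset = visited_reset,
                      action_backtrack_resamples = action_backtrack_resamples,
                      prune = prune, eps = eps)
    pred_probs[k] <- st$predictive_prob
    zg <- zg + as.integer(st$zero_guard)
    B <- st$belief
    actions_hist <- c(actions_hist, a)
    scenes_hist[[length(scenes_hist) + 1L]] <- out_sc
  }
  list(pred_probs = pred_probs, zero_guard_count = zg,
       pred_readouts = if (length(readouts)) do.call(rbind, readouts) else NULL)
}

# Compiled whole-game filter (see src/filter.cpp); identical contract.
filter_game_cpp <- function(gs, m, params, variant, visited_reset,
                            action_backtrack_resamples, prune, eps) {
  K <- length(gs$actions)
  out_label <- if (length(gs$pred_outcome_labels))
    gs$pred_outcome_labels[length(gs$pred_outcome_labels)] else -1L
  res <- cpp_filter_game(
    m$n_rows, m$n_cols, m$doors_ew, m$doors_ns,
    match(gs$actions, ACTIONS) - 1L,
    as.integer(gs$scene_labels),
    as.integer(out_label),
    as.integer(gs$pred_after),
    params$alpha, params$beta, params$p_lh, params$p_hl,
    as.integer(params$n_history),
    match(variant, c("switching", "forward_only", "efficient_only")) - 1L,
    match(visited_reset, c("window", "keep", "clear")) - 1L,
    isTRUE(action_backtrack_resamples), prune, eps)
  readouts <- NULL
  if (length(gs$pred_after)) {
    ro <- res$readouts
    readouts <- data.frame(
      c_hat = as.integer(ro[, 1L]),
      p_state_conf_high = ro[, 2L],
      map_row = as.integer(ro[, 3L]), map_col = as.integer(ro[, 4L]),
      map_ori = ORIENTATIONS[ro[, 5L] + 1L],
      pred_scene_label = as.integer(ro[, 6L]))
    dist <- ro[, 7:14, drop = FALSE]
    colnames(dist) <- paste0("p", 0:7)
    readouts <- cbind(readouts, as.data.frame(dist))
  }
  list(pred_probs = res$pred_probs,
       zero_guard_count = res$zero_guard_count,
       pred_readouts = readouts)
}
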