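#' Synthetic subject specification
#'
#' Ground-truth parameters and report-level noise models for a simulated
#' subject. The cognitive dynamics (state inference, confidence switching,
#' strategy choice, backtrack re-estimation) follow the behavioral model run
#' generatively with a single sampled hypothesis. The confidence-report and
#' reaction-time models are deliberately simple conveniences that give the
#' behavioral and decoding stages realistic inputs; they are not part of the
#' cognitive model itself.
#'
#' @param params a `model_params` (the generative ground truth).
#' @param report_fidelity probability that the reported confidence side
#'   (high = levels 3--4, low = 1--2) matches the internal binary confidence.
#' @param level_spread list with `low` (probabilities of levels 1 and 2) and
#'   `high` (levels 3 and 4) within a side.
#' @param rt_base,rt_conf_effect,rt_correct_effect,rt_sd scene-choice
#'   reaction-time model, in seconds: `rt_base` minus `rt_conf_effect` on
#'   high-confidence reports minus `rt_correct_effect` on correct choices,
#'   plus Gaussian noise with sd `rt_sd`, truncated below at 0.2 s.
#' @param rng_seed integer seed for this subject.
#' @return an object of class `agent_spec`.
#' @export
agent_spec <- function(params = model_params(),
                       report_fidelity = 0.85,
                       level_spread = list(low = c(0.5, 0.5),
                                           high = c(0.5, 0.5)),
                       rt_base = 1.8, rt_conf_effect = 0.3,
                       rt_correct_effect = 0.15, rt_sd = 0.4,
                       rng_seed = 1L) {
  stopifnot(inherits(params, "model_params"),
            report_fidelity >= 0, report_fidelity <= 1, rt_sd > 0,
            abs(sum(level_spread$low) - 1) < 1e-9,
            abs(sum(level_spread$high) - 1) < 1e-9)
  structure(list(params = params, report_fidelity = report_fidelity,
                 level_spread = level_spread, rt_base = rt_base,
                 rt_conf_effect = rt_conf_effect,
                 rt_correct_effect = rt_correct_effect, rt_sd = rt_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "agent_spec")
}

#' Generative model agent
#'
#' Runs the behavioral model forward with a single sampled hypothesis: the
#' initial state estimate is drawn uniformly from the states consistent with
#' the first scene; actions are sampled from the strategy selected by the
#' current binary confidence; after each observed outcome the operant mode is
#' classified and the state estimate, visited set and confidence are updated
#' (backtracks re-sample the state uniformly from the states consistent with
#' the recent observable window). Prediction trials are answered with the
#' scene implied by the sampled hypothesis; if that scene is not among the
#' four options the agent chooses uniformly among them (the true scene is
#' always an option, so a correct internal prediction is always expressible).
#'
#' @param m a `maze`.
#' @param spec an `agent_spec`.
#' @param rng rng stream for the agent's choices.
#' @return a list of closures implementing the [run_game()] agent interface,
#'   plus `truth_rows()` returning the per-trial hidden ground truth.
#' @export
model_agent <- function(m, spec, rng) {
  params <- spec$params
  e <- new.env(parent = emptyenv())
  e$truth <- list()

  record_truth <- function(mode) {
    e$truth[[length(e$truth) + 1L]] <- data.frame(
      true_h_row = e$h$row, true_h_col = e$h$col, true_h_ori = e$h$orientation,
      true_c = e$conf, mode = mode, stringsAsFactors = FALSE)
  }

  sample_conf <- function(p) if (rng$runif() < p[["1"]]) 1L else 0L

  # observable window for re-estimation: up to n_history actions (including
  # the pending one) plus the aligned scenes, ending at the current scene
  hist_window <- function(current_scene, pending) {
    nw <- min(params$n_history - 1L, length(e$actions))
    idx <- seq.int(length(e$actions) - nw + 1L, length.out = nw)
    list(scenes = c(e$scenes[c(idx, length(e$scenes))], list(current_scene)),
         actions = c(e$actions[idx], pending))
  }

  list(
    begin_game = function(sc) {
      cand <- candidate_states(m, sc)
      e$h <- cand[[rng$sample_int(length(cand))]]
      e$conf <- 0L
      e$visited <- cell_bit(m, e$h$row, e$h$col)
      e$scenes <- list(sc); e$actions <- character(0)
      e$pending <- NULL
      record_truth("init")
    },
    choose_action = function(sc) {
      hyp <- list(state = e$h, conf = e$conf, visited = e$visited)
      p <- policy_for(m, hyp, params, "switching")
      ACTIONS[rng$sample_int(3L, prob = p)]
    },
    notify_action = function(a) e$pending <- a,
    predict_scene = function(options) {
      lab <- scene_label(scene_of(m, transition(m, e$h, e$pending)))
      if (lab %in% options) lab else options[rng$sample_int(4L)]
    },
    report_confidence = function() {
      side <- if (rng$runif() < spec$report_fidelity) e$conf else 1L - e$conf
      if (side == 1L) 2L + rng$sample_int(2L, prob = spec$level_spread$high)
      else rng$sample_int(2L, prob = spec$level_spread$low)
    },
    report_rt = function(conf_level, correct) {
      mu <- spec$rt_base -
        spec$rt_conf_effect * as.numeric(conf_level >= 3L) -
        spec$rt_correct_effect * as.numeric(isTRUE(correct))
      max(0.2, mu + rng$rnorm(1L, 0, spec$rt_sd))
    },
    observe = function(sc) {
      a <- e$pending
      hyp <- list(state = e$h, conf = e$conf, visited = e$visited)
      mode <- classify_mode(m, hyp, a, sc)
      ct <- confidence_transition(e$conf, mode, params)
      if (mode == "backtrack") {
        win <- hist_window(sc, a)
        HS <- history_consistent_states(m, win$scenes, win$actions,
                                        detail = TRUE)
        i <- rng$sample_int(length(HS$states))
        e$h <- HS$states[[i]]
        v <- 0L
        for (j in seq_len(nrow(HS$visited[[i]])))
          v <- bitwOr(v, cell_bit(m, HS$visited[[i]][j, 1L],
                                  HS$visited[[i]][j, 2L]))
        e$visited <- v
      } else {
        e$h <- transition(m, e$h, a)
        e$visited <- bitwOr(e$visited, cell_bit(m, e$h$row, e$h$col))
      }
      e$conf <- sample_conf(ct)
      e$scenes[[length(e$scenes) + 1L]] <- sc
      e$actions <- c(e$actions, a)
      record_truth(mode)
    },
    truth_rows = function() do.call(rbind, e$truth)
  )
}

#' Simulate one synthetic subject
#'
#' Runs the generative model agent through the full task protocol and returns
#' the behavior log together with a hidden ground-truth sidecar (the agent's
#' internal state estimate, binary confidence and operant mode per trial).
#'
#' @param m a `maze`.
#' @param spec an `agent_spec`.
#' @param config a `game_config`.
#' @param subject_id identifier stamped on the log.
#' @return a `behavior_log` whose `truth` element holds the sidecar.
#' @export
simulate_subject <- function(m, spec, config, subject_id = "s1") {
  rng_env <- make_rng(derive_seed(spec$rng_seed, "env"))
  rng_agt <- make_rng(derive_seed(spec$rng_seed, "agent"))
  agent <- model_agent(m, spec, rng_agt)
  games_per_session <- split(seq_len(config$n_games),
                             ceiling(seq_len(config$n_games) *
                                       config$n_sessions / config$n_games))
  rows <- list()
  for (sess in seq_along(games_per_session))
    for (g in games_per_session[[sess]])
      rows[[length(rows) + 1L]] <- run_game(m, agent, config, rng_env,
                                            subject_id = subject_id,
                                            session = sess, game = g)
  trials <- do.call(rbind, rows)
  # align the sidecar: the agent records one snapshot per action trial
  # (begin_game / observe); a prediction trial carries the snapshot of the
  # preceding action trial, since the internal state does not change until
  # the outcome scene is observed
  tr_all <- agent$truth_rows()
  stopifnot(nrow(tr_all) == sum(trials$trial_type == "action"))
  idx <- cumsum(trials$trial_type == "action")
  truth_df <- cbind(trials[, c("subject_id", "session", "game", "trial_index",
                               "trial_type")], tr_all[idx, , drop = FALSE])
  rownames(truth_df) <- NULL
  behavior_log(trials, subject_id, config = config, truth = truth_df)
}

#' Simulate a cohort of synthetic subjects
#'
#' @param m a `maze`.
#' @param specs list of `agent_spec` (one per subject; distinct seeds give
#'   independent subjects).
#' @param config a `game_config`.
#' @return list of `behavior_log` with a `manifest` attribute (data.frame of
#'   subject ids, seeds and ground-truth parameters).
#' @export
simulate_cohort <- function(m, specs, config) {
  stopifnot(length(specs) >= 1L)
  ids <- sprintf("s%02d", seq_along(specs))
  logs <- Map(function(spec, id) simulate_subject(m, spec, config, id),
              specs, ids)
  manifest <- do.call(rbind, Map(function(spec, id) data.frame(
    subject_id = id, rng_seed = spec$rng_seed,
    alpha = spec$params$alpha, beta = spec$params$beta,
    p_lh = spec$params$p_lh, p_hl = spec$params$p_hl,
    n_history = spec$params$n_history, stringsAsFactors = FALSE),
    specs, ids))
  attr(logs, "manifest") <- manifest
  names(logs) <- ids
  logs
}
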