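#' Task protocol configuration
#'
#' Parameters of the maze navigation game: blocks of 1--5 action trials each
#' followed by one prediction trial (four-level confidence report, then a
#' choice among four scene options), repeated until the termination condition
#' -- a first-time state visit after at least `min_prediction_trials`
#' completed prediction trials -- or until `max_blocks` blocks.
#'
#' @param actions_per_block integer range (length-2) of action trials per
#'   block.
#' @param min_prediction_trials prediction trials required before the
#'   termination condition can fire.
#' @param n_games games per subject.
#' @param n_sessions scanning sessions the games are divided into.
#' @param miss_probability probability a prediction trial is missed (no
#'   confidence report or scene choice recorded).
#' @param timeout_probability probability an action trial times out, in which
#'   case the computer executes a uniformly chosen passable door.
#' @param max_blocks hard cap on blocks per game.
#' @param grid_based_termination if `TRUE`, "first-time" in the termination
#'   rule refers to the grid cell rather than the full state.
#' @param rng_seed integer seed for the task-side randomness.
#' @return an object of class `game_config`.
#' @export
game_config <- function(actions_per_block = c(1L, 5L),
                        min_prediction_trials = 5L,
                        n_games = 40L, n_sessions = 4L,
                        miss_probability = 0.007,
                        timeout_probability = 0.028,
                        max_blocks = 20L,
                        grid_based_termination = FALSE,
                        rng_seed = 1L) {
  stopifnot(length(actions_per_block) == 2L,
            actions_per_block[1L] >= 1L,
            actions_per_block[2L] >= actions_per_block[1L],
            min_prediction_trials >= 1L, n_games >= 1L, n_sessions >= 1L,
            miss_probability >= 0, miss_probability <= 1,
            timeout_probability >= 0, timeout_probability <= 1)
  structure(list(actions_per_block = as.integer(actions_per_block),
                 min_prediction_trials = as.integer(min_prediction_trials),
                 n_games = as.integer(n_games),
                 n_sessions = as.integer(n_sessions),
                 miss_probability = miss_probability,
                 timeout_probability = timeout_probability,
                 max_blocks = as.integer(max_blocks),
                 grid_based_termination = grid_based_termination,
                 rng_seed = as.integer(rng_seed)),
            class = "game_config")
}

#' Build the four scene options of a prediction trial
#'
#' The options always contain the true upcoming scene. Distractors are drawn
#' from the labels of scenes reachable by applying the selected action from
#' any state that shows the previously observed scene (local structure
#' consistent with the true state); if that pool holds fewer than three
#' distinct labels it is padded with uniformly chosen other scene labels
#' realized in the maze. Option order is randomized.
#'
#' @param m a `maze`.
#' @param prev_scene the `scene` observed on the action trial before the
#'   prediction.
#' @param action the selected action (must have been passable at the true
#'   state).
#' @param true_next_scene the `scene` of the state actually reached.
#' @param rng an rng stream (see the simulator) driving distractor sampling
#'   and option order.
#' @return integer vector of 4 distinct scene labels including the true one.
#' @export
make_scene_options <- function(m, prev_scene, action, true_next_scene, rng) {
  true_lab <- scene_label(true_next_scene)
  pool <- unique(vapply(candidate_states(m, prev_scene), function(s)
    scene_label(scene_of(m, transition(m, s, action))), integer(1)))
  pool <- setdiff(pool, true_lab)
  if (length(pool) > 3L) pool <- pool[rng$sample_int(length(pool), 3L)]
  if (length(pool) < 3L) {
    realized <- unique(vapply(all_states(m), function(s)
      scene_label(scene_of(m, s)), integer(1)))
    pad_from <- setdiff(realized, c(true_lab, pool))
    need <- 3L - length(pool)
    if (length(pad_from) < need)   # tiny mazes may realize < 4 labels
      pad_from <- c(pad_from, setdiff(1:7, c(true_lab, pool, pad_from)))
    pool <- c(pool, pad_from[rng$sample_int(length(pad_from), need)])
  }
  opts <- c(true_lab, pool)
  opts[rng$sample_int(4L, 4L)]
}

#' Game termination condition
#'
#' A game terminates when the subject is experiencing the current state for
#' the first time in the game and has completed at least
#' `min_prediction_trials` prediction trials.
#'
#' @param game_history list with `states` (list of `maze_state` experienced
#'   earlier in the game), `current` (the `maze_state` just entered) and
#'   `n_prediction_trials` (completed prediction trials).
#' @param min_prediction_trials threshold (default 5).
#' @param grid_based if `TRUE`, novelty refers to the grid cell only.
#' @return logical.
#' @export
check_termination <- function(game_history, min_prediction_trials = 5L,
                              grid_based = FALSE) {
  stopifnot(!is.null(game_history$current))
  if (game_history$n_prediction_trials < min_prediction_trials) return(FALSE)
  cur <- game_history$current
  seen <- vapply(game_history$states, function(s) {
    if (grid_based) s$row == cur$row && s$col == cur$col
    else s$row == cur$row && s$col == cur$col && s$orientation == cur$orientation
  }, logical(1))
  !any(seen)
}

#' Run one game of the task with an agent
#'
#' Starts at a uniformly random state and alternates blocks of action trials
#' (block length uniform over the configured range) with prediction trials
#' until the termination condition fires (the game then finishes its current
#' block) or `max_blocks` is reached. The action trial following a prediction
#' always presents the true next scene irrespective of the choice. Timed-out
#' actions are replaced by a computer-chosen passable door; missed prediction
#' trials carry no confidence report or scene choice.
#'
#' @param m a `maze`.
#' @param agent an agent as returned by [model_agent()] (any list providing
#'   `begin_game`, `choose_action`, `notify_action`, `predict_scene`,
#'   `report_confidence`, `report_rt`, `observe` closures).
#' @param config a `game_config`.
#' @param rng an rng stream driving the environment-side randomness.
#' @param subject_id,session,game identifiers stamped on every record.
#' @return data.frame of trial records (one row per trial).
#' @export
run_game <- function(m, agent, config, rng, subject_id = "s1",
                     session = 1L, game = 1L) {
  state <- {
    sts <- all_states(m)
    sts[[rng$sample_int(length(sts))]]
  }
  rows <- list()
  trial_index <- 0L
  n_pred <- 0L
  past_states <- list(state)
  terminate <- FALSE
  first_trial <- TRUE
  prev_scene <- NULL; prev_action <- NULL

  for (block in seq_len(config$max_blocks)) {
    k <- rng$sample_int(config$actions_per_block[2L] -
                          config$actions_per_block[1L] + 1L) +
      config$actions_per_block[1L] - 1L
    for (j in seq_len(k)) {
      trial_index <- trial_index + 1L
      sc <- scene_of(m, state)
      if (first_trial) { agent$begin_game(sc); first_trial <- FALSE }
      else agent$observe(sc)
      intended <- agent$choose_action(sc)
      timeout <- rng$runif() < config$timeout_probability
      executed <- if (timeout) {
        pa <- passable_actions(m, state)
        pa[rng$sample_int(length(pa))]
      } else intended
      agent$notify_action(executed)
      new_state <- transition(m, state, executed)
      succeeded <- !identical(format(new_state), format(state))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_id, session = session, game = game,
        block = block, trial_index = trial_index, trial_type = "action",
        state_row = state$row, state_col = state$col,
        state_ori = state$orientation,
        observed_scene_label = scene_label(sc),
        action = executed, move_succeeded = succeeded, timeout = timeout,
        opt1 = NA_integer_, opt2 = NA_integer_, opt3 = NA_integer_,
        opt4 = NA_integer_, chosen_scene_label = NA_integer_,
        true_next_scene_label = NA_integer_, correct = NA,
        confidence_report = NA_integer_, rt_scene_choice = NA_real_,
        missed = FALSE, stringsAsFactors = FALSE)
      prev_scene <- sc; prev_action <- executed
      state <- new_state
      if (!terminate &&
          check_termination(list(states = past_states, current = state,
                                 n_prediction_trials = n_pred),
                            config$min_prediction_trials,
                            config$grid_based_termination))
        terminate <- TRUE
      past_states[[length(past_states) + 1L]] <- state
    }
    # prediction trial about the scene of the state just reached
    trial_index <- trial_index + 1L
    true_next <- scene_of(m, state)
    opts <- make_scene_options(m, prev_scene, prev_action, true_next, rng)
    missed <- rng$runif() < config$miss_probability
    if (missed) {
      chosen <- NA_integer_; conf <- NA_integer_; rt <- NA_real_; corr <- NA
    } else {
      conf <- agent$report_confidence()
      chosen <- agent$predict_scene(opts)
      corr <- chosen == scene_label(true_next)
      rt <- agent$report_rt(conf, corr)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subject_id, session = session, game = game,
      block = block, trial_index = trial_index, trial_type = "prediction",
      state_row = state$row, state_col = state$col,
      state_ori = state$orientation,
      observed_scene_label = NA_integer_,
      action = NA_character_, move_succeeded = NA, timeout = FALSE,
      opt1 = opts[1L], opt2 = opts[2L], opt3 = opts[3L], opt4 = opts[4L],
      chosen_scene_label = chosen,
      true_next_scene_label = scene_label(true_next), correct = corr,
      confidence_report = conf, rt_scene_choice = rt,
      missed = missed, stringsAsFactors = FALSE)
    n_pred <- n_pred + 1L
    if (terminate) break
  }
  do.call(rbind, rows)
}

## ---- behavior log container and I/O ---------------------------------------

#' Behavior log of one subject
#'
#' @param trials data.frame of trial records (as produced by [run_game()]).
#' @param subject_id identifier.
#' @param config the `game_config` used (or `NULL`).
#' @param truth optional hidden ground-truth sidecar (internal state,
#'   confidence and mode per trial) from the simulator.
#' @return an object of class `behavior_log`.
#' @export
behavior_log <- function(trials, subject_id, config = NULL, truth = NULL) {
  structure(list(trials = trials, subject_id = subject_id,
                 config = config, truth = truth),
            class = "behavior_log")
}

#' @export
print.behavior_log <- function(x, ...) {
  cat(sprintf("<behavior_log %s: %d trials, %d games, %d prediction trials>\n",
              x$subject_id, nrow(x$trials), length(unique(x$trials$game)),
              sum(x$trials$trial_type == "prediction")))
  invisible(x)
}

#' Read / write behavior logs as CSV
#'
#' One row per trial, columns exactly the trial-record fields (missing values
#' empty). The configuration is stored in a JSON sidecar `<path>.json`, and
#' the simulator's hidden ground truth (when present) in
#' `<path stem>_truth.csv`, so a written log round-trips losslessly.
#'
#' @param log a `behavior_log`.
#' @param path CSV file path.
#' @return `read_behavior_log` returns a `behavior_log`; the writer returns
#'   `path` invisibly.
#' @export
write_behavior_log <- function(log, path) {
  utils::write.csv(log$trials, path, row.names = FALSE, na = "")
  if (!is.null(log$config))
    jsonlite::write_json(c(list(subject_id = log$subject_id),
                           unclass(log$config)),
                         paste0(path, ".json"), auto_unbox = TRUE)
  if (!is.null(log$truth))
    utils::write.csv(log$truth, sub("\\.csv$", "_truth.csv", path),
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_behavior_log
#' @export
read_behavior_log <- function(path) {
  tr <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  tr$trial_type <- as.character(tr$trial_type)
  cfg <- NULL
  if (file.exists(paste0(path, ".json"))) {
    x <- jsonlite::fromJSON(paste0(path, ".json"))
    sid <- x$subject_id; x$subject_id <- NULL
    cfg <- do.call(game_config, list(
      actions_per_block = as.integer(x$actions_per_block),
      min_prediction_trials = x$min_prediction_trials,
      n_games = x$n_games, n_sessions = x$n_sessions,
      miss_probability = x$miss_probability,
      timeout_probability = x$timeout_probability,
      max_blocks = x$max_blocks,
      grid_based_termination = x$grid_based_termination,
      rng_seed = x$rng_seed))
  }
  truth_path <- sub("\\.csv$", "_truth.csv", path)
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, na.strings = "", stringsAsFactors = FALSE)
  else NULL
  behavior_log(tr, subject_id = tr$subject_id[1L], config = cfg, truth = truth)
}
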