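#' Behavioral model parameters
#'
#' The hidden Markov behavioral model has five parameters: `alpha`, the
#' probability of choosing the optimal action under the forward-dominant
#' strategy (used at low state confidence); `beta`, the optimal-action
#' probability under the efficient-exploration strategy (high state
#' confidence); `p_lh`, the probability that low state confidence switches to
#' high after a confirmed scene prediction (update mode); `p_hl`, the
#' probability that high confidence switches to low after a violated
#' prediction (backtrack mode); and `n_history`, the number of past
#' (scene, action) steps used to re-estimate the state after a backtrack.
#'
#' @param alpha,beta,p_lh,p_hl probabilities in \[0, 1\].
#' @param n_history positive integer window length.
#' @return an object of class `model_params`.
#' @export
model_params <- function(alpha = 0.9, beta = 0.85, p_lh = 0.4, p_hl = 0.5,
                         n_history = 2L) {
  for (p in c(alpha, beta, p_lh, p_hl))
    if (!is.finite(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (n_history < 1L) stop("n_history must be >= 1")
  structure(list(alpha = alpha, beta = beta, p_lh = p_lh, p_hl = p_hl,
                 n_history = as.integer(n_history)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params alpha=%.3f beta=%.3f p_lh=%.3f p_hl=%.3f n=%d>\n",
              x$alpha, x$beta, x$p_lh, x$p_hl, x$n_history))
  invisible(x)
}

## ---- hypotheses and beliefs ------------------------------------------------

# visited grids are kept as 32-bit masks: bit (row * n_cols + col) set iff the
# hypothesis believes it has visited that cell; limits the grid to 30 cells
cell_bit <- function(m, row, col) bitwShiftL(1L, row * m$n_cols + col)

check_mask_capacity <- function(m) {
  if (m$n_rows * m$n_cols > 30L)
    stop("belief filtering supports mazes of at most 30 cells")
}

new_hypothesis <- function(state, conf, mode, visited, weight) {
  list(state = state, conf = as.integer(conf), mode = mode,
       visited = as.integer(visited), weight = weight)
}

hypothesis_key <- function(h) {
  paste(format(h$state), h$conf, h$mode, h$visited, sep = "|")
}

#' Initial belief from the first observed scene
#'
#' One hypothesis per state consistent with the first scene, each with weight
#' `1/|H_1|`, low state confidence with probability one, update mode, and a
#' visited set containing only its own cell.
#'
#' @param m a `maze`.
#' @param first_scene a `scene` realized in the maze.
#' @return an object of class `belief_state`.
#' @export
init_belief <- function(m, first_scene) {
  check_mask_capacity(m)
  cand <- candidate_states(m, first_scene)
  if (!length(cand))
    stop("inconsistent observation: no state in the maze shows this scene")
  w <- 1 / length(cand)
  hyps <- lapply(cand, function(s)
    new_hypothesis(s, 0L, "update", cell_bit(m, s$row, s$col), w))
  structure(list(hypotheses = hyps, trial_index = 1L), class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("<belief_state: %d hypotheses at trial %d>\n",
              length(x$hypotheses), x$trial_index))
  invisible(x)
}

belief_weights <- function(b) vapply(b$hypotheses, `[[`, numeric(1), "weight")

## ---- action strategies -----------------------------------------------------

passable_actions <- function(m, s) {
  sc <- scene_of(m, s)
  ACTIONS[c(sc$left, sc$forward, sc$right)]
}

#' Forward-dominant action strategy (low state confidence)
#'
#' An information-maximizing policy: move forward if the forward door is open;
#' if forward is closed and both side doors are open, prefer the right; with a
#' single open door, take it. The optimal action receives probability `alpha`,
#' each other passable action `(1 - alpha) / N_nopt`; with no passable
#' non-optimal action the optimal action receives probability one.
#'
#' @param m a `maze`.
#' @param hyp a hypothesis: a list with at least `state` (a `maze_state`).
#' @param params a `model_params`.
#' @return named numeric distribution over `"left"`, `"forward"`, `"right"`
#'   (zero for impassable directions).
#' @export
forward_dominant_policy <- function(m, hyp, params) {
  pa <- passable_actions(m, hyp$state)
  if (!length(pa)) stop("state has no passable door; maze invariant violated")
  opt <- if ("forward" %in% pa) "forward"
         else if (all(c("left", "right") %in% pa)) "right"
         else pa[1L]
  dist_from_optimal(pa, opt, params$alpha)
}

#' Efficient-exploration action strategy (high state confidence)
#'
#' Prefers doors leading to cells the hypothesis has not yet visited; when
#' every accessible neighbor has been visited, the optimal actions are those
#' starting a shortest open-door path to the nearest unexplored cell (all tied
#' actions optimal). Optimal actions share probability `beta`; passable
#' non-optimal actions share `1 - beta`; with no non-optimal passable action
#' the optimal set is renormalized to probability one. If every cell has been
#' visited, all passable actions are treated as optimal.
#'
#' @inheritParams forward_dominant_policy
#' @param hyp list with `state` (a `maze_state`) and `visited` (integer
#'   bitmask of visited cells, bit `row * n_cols + col`).
#' @return named numeric distribution over actions.
#' @export
efficient_exploration_policy <- function(m, hyp, params) {
  pa <- passable_actions(m, hyp$state)
  if (!length(pa)) stop("state has no passable door; maze invariant violated")
  if (length(pa) == 1L) return(dist_from_optimal(pa, pa, 1))
  dest <- lapply(pa, function(a) transition(m, hyp$state, a))
  unvis <- vapply(dest, function(d)
    bitwAnd(hyp$visited, cell_bit(m, d$row, d$col)) == 0L, logical(1))
  if (any(unvis)) {
    opt <- pa[unvis]
  } else {
    dmat <- unvisited_distance(m, hyp$visited)
    if (all(is.infinite(dmat))) {
      opt <- pa
    } else {
      dd <- vapply(dest, function(d) dmat[d$row + 1L, d$col + 1L], numeric(1))
      opt <- pa[dd == min(dd)]
    }
  }
  dist_from_optimal(pa, opt, params$beta)
}

# shared mass assignment: optimal actions split p_opt, the rest split 1 - p_opt
dist_from_optimal <- function(passable, optimal, p_opt) {
  out <- stats::setNames(numeric(3L), ACTIONS)
  nopt <- setdiff(passable, optimal)
  if (!length(nopt)) out[optimal] <- 1 / length(optimal)
  else {
    out[optimal] <- p_opt / length(optimal)
    out[nopt] <- (1 - p_opt) / length(nopt)
  }
  out
}

# grid-graph breadth-first distance from every cell to the nearest unvisited
# cell (0 on unvisited cells, Inf when the whole maze has been visited)
unvisited_distance <- function(m, visited_mask) {
  R <- m$n_rows; C <- m$n_cols
  d <- matrix(Inf, R, C)
  q <- list(); head <- 1L
  for (r in seq_len(R) - 1L) for (c in seq_len(C) - 1L)
    if (bitwAnd(visited_mask, cell_bit(m, r, c)) == 0L) {
      d[r + 1L, c + 1L] <- 0
      q[[length(q) + 1L]] <- c(r, c)
    }
  while (head <= length(q)) {
    rc <- q[[head]]; head <- head + 1L
    r <- rc[1L]; c <- rc[2L]
    for (dir in ORIENTATIONS) {
      if (!door_open(m, r, c, dir)) next
      nb <- step_cell(r, c, dir)
      if (d[nb[1L] + 1L, nb[2L] + 1L] > d[r + 1L, c + 1L] + 1) {
        d[nb[1L] + 1L, nb[2L] + 1L] <- d[r + 1L, c + 1L] + 1
        q[[length(q) + 1L]] <- nb
      }
    }
  }
  d
}

policy_for <- function(m, hyp, params, variant) {
  switch(variant,
    switching = if (hyp$conf == 1L) efficient_exploration_policy(m, hyp, params)
                else forward_dominant_policy(m, hyp, params),
    forward_only = forward_dominant_policy(m, hyp, params),
    efficient_only = efficient_exploration_policy(m, hyp, params),
    stop("unknown model variant: ", variant))
}

## ---- confidence dynamics ---------------------------------------------------

#' Markov transition of the binary state confidence
#'
#' In update mode (prediction confirmed) low confidence switches to high with
#' probability `p_lh` and high confidence stays high. In backtrack mode
#' (prediction violated) high confidence switches to low with probability
#' `p_hl` and low confidence stays low.
#'
#' @param confidence current level, 0 (low) or 1 (high).
#' @param mode `"update"` or `"backtrack"` (the exceptional
#'   `"action_backtrack"` uses the backtrack matrix, `"forced_update"` the
#'   update matrix).
#' @param params a `model_params`.
#' @return named numeric vector: probabilities of next confidence `0` and `1`.
#' @export
confidence_transition <- function(confidence, mode, params) {
  confidence <- as.integer(confidence)
  stopifnot(confidence %in% c(0L, 1L))
  use_bt <- mode %in% c("backtrack", "action_backtrack")
  if (!use_bt && !mode %in% c("update", "forced_update"))
    stop("unknown mode: ", mode)
  if (use_bt) {
    if (confidence == 0L) c(`0` = 1, `1` = 0)
    else c(`0` = params$p_hl, `1` = 1 - params$p_hl)
  } else {
    if (confidence == 0L) c(`0` = 1 - params$p_lh, `1` = params$p_lh)
    else c(`0` = 0, `1` = 1)
  }
}

#' Classify the operant mode of a hypothesis after an action
#'
#' Compares the scene the hypothesis predicted for its next state against the
#' actually observed scene. A mismatch is a backtrack (the previous inference
#' is discarded). A match whose destination cell was already visited, and is a
#' different cell than the current one, marks inefficient exploration
#' (action-backtrack) -- unless every passable door led to a visited cell, in
#' which case revisiting was unavoidable and the step counts as a (forced)
#' update.
#'
#' @param m a `maze`.
#' @param hyp hypothesis (list with `state` and `visited` bitmask).
#' @param action the executed action.
#' @param next_scene the observed next scene.
#' @return one of `"update"`, `"backtrack"`, `"action_backtrack"`,
#'   `"forced_update"`.
#' @export
classify_mode <- function(m, hyp, action, next_scene) {
  h2 <- transition(m, hyp$state, action)
  if (!scene_equal(scene_of(m, h2), next_scene)) return("backtrack")
  same_cell <- h2$row == hyp$state$row && h2$col == hyp$state$col
  revisit <- bitwAnd(hyp$visited, cell_bit(m, h2$row, h2$col)) != 0L
  if (revisit && !same_cell) {
    pa <- passable_actions(m, hyp$state)
    dests_visited <- vapply(pa, function(a) {
      d <- transition(m, hyp$state, a)
      bitwAnd(hyp$visited, cell_bit(m, d$row, d$col)) != 0L
    }, logical(1))
    if (all(dests_visited)) "forced_update" else "action_backtrack"
  } else "update"
}

## ---- the incremental Bayesian filter ---------------------------------------

# Phase 1 of a filtering step: condition the belief on the observed action.
# Returns the reweighted belief and the predictive action probability
# (the model-evidence factor), computed BEFORE renormalization.
condition_on_action <- function(belief, action, m, params, variant = "switching",
                                eps = 1e-10) {
  L <- vapply(belief$hypotheses, function(h)
    unname(policy_for(m, h, params, variant)[action]), numeric(1))
  w <- belief_weights(belief)
  pred <- sum(w * L)
  zero_guard <- pred <= 0
  if (zero_guard) { L <- rep(1, length(L)); pred <- eps }
  w2 <- w * L / sum(w * L)
  hyps <- belief$hypotheses
  for (i in seq_along(hyps)) hyps[[i]]$weight <- w2[i]
  list(belief = structure(list(hypotheses = hyps,
                               trial_index = belief$trial_index),
                          class = "belief_state"),
       predictive_prob = pred, zero_guard = zero_guard)
}

# Phase 2: propagate each hypothesis through the observed outcome scene.
observe_outcome <- function(belief, action, next_scene, m, params,
                            history = NULL, variant = "switching",
                            visited_reset = c("window", "keep", "clear"),
                            action_backtrack_resamples = FALSE,
                            prune = 1e-8) {
  visited_reset <- match.arg(visited_reset)
  # the re-estimated state set is shared by all hypotheses (it depends only on
  # the observable history window), so compute it at most once
  Hset <- NULL
  get_Hset <- function() {
    if (is.null(Hset)) {
      if (is.null(history))
        history <- list(scenes = list(next_scene), actions = character(0))
      Hset <<- history_consistent_states(m, history$scenes, history$actions,
                                         detail = TRUE)
    }
    Hset
  }
  acc <- new.env(parent = emptyenv())
  add <- function(h) {
    key <- hypothesis_key(h)
    if (is.null(acc[[key]])) acc[[key]] <- h
    else acc[[key]]$weight <- acc[[key]]$weight + h$weight
  }
  for (h in belief$hypotheses) {
    mode <- classify_mode(m, h, action, next_scene)
    ct <- confidence_transition(h$conf, mode, params)
    resample <- mode == "backtrack" ||
      (mode == "action_backtrack" && action_backtrack_resamples)
    if (!resample) {
      h2 <- transition(m, h$state, action)
      vis <- bitwOr(h$visited, cell_bit(m, h2$row, h2$col))
      for (cc in c(0L, 1L)) if (ct[[as.character(cc)]] > 0)
        add(new_hypothesis(h2, cc, mode, vis,
                           h$weight * ct[[as.character(cc)]]))
    } else {
      HS <- get_Hset()
      k <- length(HS$states)
      if (k == 0L) stop("re-estimation set empty; log inconsistent with maze")
      for (i in seq_len(k)) {
        s2 <- HS$states[[i]]
        vis <- switch(visited_reset,
          window = {
            v <- 0L
            for (j in seq_len(nrow(HS$visited[[i]])))
              v <- bitwOr(v, cell_bit(m, HS$visited[[i]][j, 1L],
                                      HS$visited[[i]][j, 2L]))
            v
          },
          keep = bitwOr(h$visited, cell_bit(m, s2$row, s2$col)),
          clear = cell_bit(m, s2$row, s2$col))
        for (cc in c(0L, 1L)) if (ct[[as.character(cc)]] > 0)
          add(new_hypothesis(s2, cc, mode, vis,
                             h$weight * ct[[as.character(cc)]] / k))
      }
    }
  }
  hyps <- as.list(acc)
  hyps <- unname(hyps[order(names(hyps))])
  w <- vapply(hyps, `[[`, numeric(1), "weight")
  keep <- w / sum(w) >= prune
  hyps <- hyps[keep]; w <- w[keep]; w <- w / sum(w)
  for (i in seq_along(hyps)) hyps[[i]]$weight <- w[i]
  structure(list(hypotheses = hyps, trial_index = belief$trial_index + 1L),
            class = "belief_state")
}

#' One step of the incremental Bayesian filter
#'
#' Conditions the belief on the observed action (each hypothesis's likelihood
#' is the probability its confidence-appropriate strategy assigns to that
#' action) and then propagates every hypothesis through the observed outcome
#' scene: confirmed predictions move deterministically and update confidence
#' through the update-mode matrix; violated predictions (backtrack) re-estimate
#' the state uniformly over the states consistent with the recent observable
#' window and update confidence through the backtrack matrix. Hypotheses with
#' identical (state, confidence, mode, visited-set) keys are merged and
#' weights below `prune` are dropped before renormalization.
#'
#' @param belief a normalized `belief_state`.
#' @param action the executed action.
#' @param next_scene the `scene` observed after the action.
#' @param m a `maze`.
#' @param params a `model_params`.
#' @param history observable window for backtrack re-estimation: a list with
#'   `scenes` (list of `scene`, oldest first, ending with `next_scene`) and
#'   `actions` (character vector, one per step; at most `params$n_history`).
#'   `NULL` degrades to re-estimation from `next_scene` alone.
#' @param variant `"switching"` (strategy chosen by confidence),
#'   `"forward_only"` or `"efficient_only"`.
#' @param visited_reset what a re-estimated hypothesis believes it has
#'   visited: the cells traversed by the consistent window trajectories
#'   (`"window"`, default), its previous visited set (`"keep"`), or only the
#'   new cell (`"clear"`).
#' @param action_backtrack_resamples if `TRUE` the action-backtrack exception
#'   also re-estimates the state; by default it keeps the (confirmed)
#'   deterministic move and only applies the backtrack confidence matrix.
#' @param prune relative weight threshold below which hypotheses are dropped.
#' @param eps floor for the predictive action probability when no surviving
#'   hypothesis allows the observed action.
#' @return list with `belief` (the posterior), `predictive_prob` (the
#'   model-evidence factor for this action, computed before normalization) and
#'   `zero_guard` (whether the floor was hit).
#' @export
step_filter <- function(belief, action, next_scene, m, params,
                        history = NULL, variant = "switching",
                        visited_reset = "window",
                        action_backtrack_resamples = FALSE,
                        prune = 1e-8, eps = 1e-10) {
  ph1 <- condition_on_action(belief, action, m, params, variant, eps)
  post <- observe_outcome(ph1$belief, action, next_scene, m, params,
                          history = history, variant = variant,
                          visited_reset = visited_reset,
                          action_backtrack_resamples = action_backtrack_resamples,
                          prune = prune)
  list(belief = post, predictive_prob = ph1$predictive_prob,
       zero_guard = ph1$zero_guard)
}

## ---- read-outs -------------------------------------------------------------

#' Most probable next action(s) under the belief
#'
#' Marginalizes the confidence-appropriate strategy over all hypotheses and
#' returns every action attaining the maximal probability (ties are returned
#' as a set, not broken).
#'
#' @inheritParams step_filter
#' @param tol tie tolerance.
#' @return character vector of predicted actions.
#' @export
predict_action <- function(belief, m, params, variant = "switching",
                           tol = 1e-12) {
  p <- marginal_action_dist(belief, m, params, variant)
  names(p)[p >= max(p) - tol]
}

#' @rdname predict_action
#' @export
marginal_action_dist <- function(belief, m, params, variant = "switching") {
  p <- stats::setNames(numeric(3L), ACTIONS)
  for (h in belief$hypotheses)
    p <- p + h$weight * policy_for(m, h, params, variant)
  p
}

#' Predictive distribution over upcoming scene labels
#'
#' Pushes every hypothesis through the taken action and the maze dynamics and
#' accumulates weight on the scene label it would then observe.
#'
#' @inheritParams step_filter
#' @param action the action just taken.
#' @param rng optional rng stream (as from the simulator) used to break ties
#'   at the argmax; with `NULL` the lowest label wins.
#' @return list with `dist` (named numeric over labels 0..7, summing to 1)
#'   and `label` (the modal predicted label).
#' @export
predict_scene_dist <- function(belief, action, m, rng = NULL) {
  p <- stats::setNames(numeric(8L), as.character(0:7))
  for (h in belief$hypotheses) {
    lab <- scene_label(scene_of(m, transition(m, h$state, action)))
    p[[as.character(lab)]] <- p[[as.character(lab)]] + h$weight
  }
  top <- which(p >= max(p) - 1e-12)
  pick <- if (length(top) > 1L && !is.null(rng)) top[rng$sample_int(length(top))]
          else top[1L]
  list(dist = p, label = as.integer(names(p)[pick]))
}

#' Binary state-confidence estimate from a belief
#'
#' Low (0) unless the largest joint mass P(confidence = 1, state), taken over
#' the states with maximal marginal state probability, strictly exceeds the
#' total mass at confidence 0; an exact tie yields 0.
#'
#' @inheritParams step_filter
#' @return integer 0 or 1.
#' @export
estimate_state_confidence <- function(belief) {
  keys <- vapply(belief$hypotheses, function(h) format(h$state), character(1))
  w <- belief_weights(belief)
  conf <- vapply(belief$hypotheses, `[[`, integer(1), "conf")
  ph <- tapply(w, keys, sum)
  top_states <- names(ph)[ph >= max(ph) - 1e-12]
  in_top <- keys %in% top_states
  p1_by_state <- tapply(w[conf == 1L & in_top], keys[conf == 1L & in_top], sum)
  max_p1 <- if (length(p1_by_state)) max(p1_by_state) else 0
  p0_total <- sum(w[conf == 0L])
  if (max_p1 <= p0_total) 0L else 1L
}

# maximum a posteriori state of a belief (marginal over confidence/mode);
# ties broken by the lowest (row, col, orientation) linear index
map_state <- function(belief) {
  idx <- vapply(belief$hypotheses, function(h)
    (h$state$row * 1000L + h$state$col) * 4L +
      match(h$state$orientation, ORIENTATIONS), integer(1))
  w <- belief_weights(belief)
  ph <- tapply(w, idx, sum)
  top <- names(ph)[ph >= max(ph) - 1e-12]
  best <- min(as.integer(top))
  belief$hypotheses[[match(best, idx)]]$state
}
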