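# Exhaustive trajectory-enumeration oracle for the belief filter.
#
# Enumerates every cognitive-state trajectory (state, confidence,
# visited-set) compatible with an observed action/scene sequence, carrying
# full product weights with no merging and no pruning, and derives the
# per-step predictive action probabilities and the terminal posterior over
# (state, confidence). The filter must reproduce these exactly (up to
# floating-point tolerance); see the oracle-equivalence tests.
#
# Visited sets are kept as sorted integer cell-id vectors (not bitmasks) and
# window consistency is re-derived by inline simulation, so the bookkeeping
# is independent of the implementation under test.

oracle_filter <- function(m, scenes, actions, params,
                          variant = "switching") {
  cell_id <- function(s) s$row * m$n_cols + s$col
  # trajectory: h (state), conf, vis (sorted cell ids), w (joint probability)
  trajs <- lapply(candidate_states(m, scenes[[1]]), function(s)
    list(h = s, conf = 0L, vis = cell_id(s), w = 1 / length(candidate_states(m, scenes[[1]]))))

  window_states <- function(t_next) {
    # states (with traversed-cell unions) consistent with the last
    # min(n_history, t_next - 1) actions ending at scene t_next
    k <- min(params$n_history, t_next - 1)
    first <- t_next - k
    out <- list()
    for (s0 in candidate_states(m, scenes[[first]])) {
      s <- s0; cells <- cell_id(s0); ok <- TRUE
      for (i in seq.int(first, t_next - 1)) {
        s <- transition(m, s, actions[[i]])
        cells <- union(cells, cell_id(s))
        if (scene_label(scene_of(m, s)) != scene_label(scenes[[i + 1]])) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      key <- format(s)
      if (is.null(out[[key]])) out[[key]] <- list(s = s, cells = cells)
      else out[[key]]$cells <- union(out[[key]]$cells, cells)
    }
    unname(out)
  }

  pred_probs <- numeric(length(actions))
  for (t in seq_along(actions)) {
    a <- actions[[t]]
    # predictive probability of the observed action
    tw <- sum(vapply(trajs, `[[`, numeric(1), "w"))
    lik <- vapply(trajs, function(tr) {
      hyp <- list(state = tr$h, conf = tr$conf,
                  visited = sum(bitwShiftL(1L, tr$vis)))
      unname(policy_for_test(m, hyp, params, variant)[a])
    }, numeric(1))
    pred_probs[t] <- sum(vapply(trajs, `[[`, numeric(1), "w") * lik) / tw
    # branch every trajectory through the observed outcome
    next_sc <- scenes[[t + 1]]
    win <- NULL
    new_trajs <- list()
    for (i in seq_along(trajs)) {
      tr <- trajs[[i]]
      w <- tr$w * lik[i]
      if (w == 0) next
      h2 <- transition(m, tr$h, a)
      match_sc <- scene_label(scene_of(m, h2)) == scene_label(next_sc)
      if (!match_sc) {
        mode <- "backtrack"
      } else {
        revisit <- cell_id(h2) %in% tr$vis &&
          cell_id(h2) != cell_id(tr$h)
        if (revisit) {
          sc_here <- scene_of(m, tr$h)
          pa <- c("left", "forward", "right")[c(sc_here$left, sc_here$forward,
                                                sc_here$right)]
          dests <- vapply(pa, function(aa)
            cell_id(transition(m, tr$h, aa)) %in% tr$vis, logical(1))
          mode <- if (all(dests)) "forced_update" else "action_backtrack"
        } else mode <- "update"
      }
      ct <- if (mode %in% c("backtrack", "action_backtrack")) {
        if (tr$conf == 0L) c(1, 0) else c(params$p_hl, 1 - params$p_hl)
      } else {
        if (tr$conf == 0L) c(1 - params$p_lh, params$p_lh) else c(0, 1)
      }
      emit <- function(h, vis, cc, ww) {
        new_trajs[[length(new_trajs) + 1]] <<-
          list(h = h, conf = cc, vis = sort(unique(vis)), w = ww)
      }
      if (mode == "backtrack") {
        if (is.null(win)) win <- window_states(t + 1)
        for (ws in win) for (cc in c(0L, 1L)) if (ct[cc + 1] > 0)
          emit(ws$s, ws$cells, cc, w * ct[cc + 1] / length(win))
      } else {
        for (cc in c(0L, 1L)) if (ct[cc + 1] > 0)
          emit(h2, c(tr$vis, cell_id(h2)), cc, w * ct[cc + 1])
      }
    }
    trajs <- new_trajs
  }
  # terminal posterior over (state, confidence)
  w <- vapply(trajs, `[[`, numeric(1), "w")
  keys <- vapply(trajs, function(tr) paste(format(tr$h), tr$conf), character(1))
  post <- tapply(w, keys, sum)
  post <- post / sum(post)
  list(pred_probs = pred_probs, posterior = post)
}

# the policies themselves are certified by hand-worked examples elsewhere;
# the oracle reuses the package policy so that it exercises exactly the
# Bayesian bookkeeping (branching, merging, normalization) of the filter
policy_for_test <- function(m, hyp, params, variant) {
  if (variant == "forward_only" ||
      (variant == "switching" && hyp$conf == 0L))
    forward_dominant_policy(m, hyp, params)
  else efficient_exploration_policy(m, hyp, params)
}

# posterior over (state, confidence) from a belief_state, keyed like the oracle
belief_posterior <- function(belief) {
  w <- vapply(belief$hypotheses, `[[`, numeric(1), "weight")
  keys <- vapply(belief$hypotheses, function(h)
    paste(format(h$state), h$conf), character(1))
  post <- tapply(w, keys, sum)
  post / sum(post)
}

# drive step_filter over an observed walk, reproducing the window bookkeeping
# of the whole-log driver
run_step_filter <- function(m, scenes, actions, params,
                            variant = "switching", prune = 1e-300) {
  B <- init_belief(m, scenes[[1]])
  pred <- numeric(length(actions))
  for (t in seq_along(actions)) {
    nw <- min(params$n_history - 1L, t - 1L)
    idx <- seq.int(t - nw, length.out = nw)
    history <- list(scenes = c(scenes[c(idx, t)], list(scenes[[t + 1]])),
                    actions = c(actions[idx], actions[[t]]))
    st <- step_filter(B, actions[[t]], scenes[[t + 1]], m, params,
                      history = history, variant = variant, prune = prune)
    pred[t] <- st$predictive_prob
    B <- st$belief
  }
  list(belief = B, pred_probs = pred)
}
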