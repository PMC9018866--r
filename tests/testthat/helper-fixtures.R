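# Fixture mazes and small shared utilities, built in code.

# fully open 3x3 grid: highly ambiguous scenes, useful for symmetry checks
fixture_maze_open3 <- function() {
  maze(3, 3,
       doors_ew = matrix(TRUE, 3, 2),
       doors_ns = matrix(TRUE, 2, 3))
}

# 3x3 maze with two closed interior doors; realizes all seven scene types,
# with label 7 rare (exactly two states)
fixture_maze_b3 <- function() {
  maze(3, 3,
       doors_ew = matrix(c(TRUE, TRUE,
                           FALSE, TRUE,
                           TRUE, TRUE), 3, 2, byrow = TRUE),
       doors_ns = matrix(c(TRUE, TRUE, TRUE,
                           TRUE, FALSE, TRUE), 2, 3, byrow = TRUE))
}

# the 5x5 maze used for cohort-level checks
fixture_maze_5 <- function() generate_maze(5, 5, seed = 42)

default_theta <- function() model_params(0.9, 0.85, 0.4, 0.5, 2)

# independent scene computation straight from the door matrices (no package
# scene/transition code): used to certify scene_of by exhaustive tabulation
raw_door_open <- function(m, r, c, dir) {
  # r, c 0-based; dir in N/E/S/W
  switch(dir,
         N = r >= 1 && m$doors_ns[r, c + 1],
         S = r <= m$n_rows - 2 && m$doors_ns[r + 1, c + 1],
         E = c <= m$n_cols - 2 && m$doors_ew[r + 1, c + 1],
         W = c >= 1 && m$doors_ew[r + 1, c])
}

raw_scene <- function(m, r, c, ori) {
  dirs <- c("N", "E", "S", "W")
  i <- match(ori, dirs)
  left <- dirs[(i - 2) %% 4 + 1]
  right <- dirs[i %% 4 + 1]
  c(left = raw_door_open(m, r, c, left),
    forward = raw_door_open(m, r, c, ori),
    right = raw_door_open(m, r, c, right))
}

# random observable walk through a maze: true dynamics, arbitrary action
# choices (occasionally through closed doors, which no-op)
random_walk <- function(m, n_steps, seed, p_closed_attempt = 0.15) {
  set.seed(seed)
  sts <- all_states(m)
  s <- sts[[sample.int(length(sts), 1)]]
  scenes <- list(scene_of(m, s))
  actions <- character(0)
  for (i in seq_len(n_steps)) {
    sc <- scene_of(m, s)
    open <- c("left", "forward", "right")[c(sc$left, sc$forward, sc$right)]
    closed <- setdiff(c("left", "forward", "right"), open)
    a <- if (length(closed) && runif(1) < p_closed_attempt)
      closed[sample.int(length(closed), 1)]
    else open[sample.int(length(open), 1)]
    s <- transition(m, s, a)
    actions <- c(actions, a)
    scenes[[length(scenes) + 1]] <- scene_of(m, s)
  }
  list(scenes = scenes, actions = actions)
}

# minimal hypothesis constructor for read-out tests (visited set: own cell,
# assuming a 3-column fixture maze)
new_hyp_for_test <- function(state, weight) {
  list(state = state, conf = 0L, mode = "update",
       visited = bitwShiftL(1L, state$row * 3L + state$col),
       weight = weight)
}

# tiny simulated subject shared by several test files
quick_log <- function(n_games = 4, seed = 7, m = fixture_maze_5(),
                      params = default_theta()) {
  simulate_subject(m, agent_spec(params = params, rng_seed = seed),
                   game_config(n_games = n_games, n_sessions = 2,
                               rng_seed = seed + 1))
}
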