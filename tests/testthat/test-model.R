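# The hidden Markov behavioral model: belief initialization, the two action
# strategies, confidence dynamics, operant-mode classification, and the
# incremental Bayesian filter, certified against exhaustive trajectory
# enumeration on small mazes.

test_that("the initial belief is uniform over scene-consistent states at low confidence", {
  m <- fixture_maze_b3()
  sc <- scene(TRUE, FALSE, TRUE)
  B <- init_belief(m, sc)
  cand <- candidate_states(m, sc)
  expect_length(B$hypotheses, length(cand))
  ws <- vapply(B$hypotheses, `[[`, numeric(1), "weight")
  expect_equal(ws, rep(1 / length(cand), length(cand)))
  expect_true(all(vapply(B$hypotheses, `[[`, integer(1), "conf") == 0L))
  expect_setequal(vapply(B$hypotheses, function(h) format(h$state), character(1)),
                  vapply(cand, format, character(1)))
  # a scene the maze cannot show
  expect_error(init_belief(fixture_maze_open3(), scene(FALSE, TRUE, FALSE)),
               "inconsistent observation")
})

test_that("the forward-dominant strategy prefers forward, then right, then the only door", {
  m <- fixture_maze_open3()
  params <- model_params(alpha = 0.7)
  # center cell: all three visible doors open
  h_all <- list(state = maze_state(1, 1, "N"), conf = 0L, visited = 0L)
  expect_equal(forward_dominant_policy(m, h_all, params),
               c(left = 0.15, forward = 0.7, right = 0.15))
  # facing the wall with both side doors open: right is optimal
  h_lr <- list(state = maze_state(0, 1, "N"), conf = 0L, visited = 0L)
  expect_equal(forward_dominant_policy(m, h_lr, params),
               c(left = 0.3, forward = 0, right = 0.7))
  # corner facing the wall: a single passable door gets everything
  h_one <- list(state = maze_state(0, 0, "N"), conf = 0L, visited = 0L)
  expect_equal(forward_dominant_policy(m, h_one, params),
               c(left = 0, forward = 0, right = 1))
})

test_that("the efficient-exploration strategy seeks unvisited cells and shortest paths", {
  m <- fixture_maze_open3()
  params <- model_params(beta = 0.8)
  bit <- function(r, c) bitwShiftL(1L, r * 3L + c)
  # at (0,1) facing S: left -> (0,0)... egocentric: left of S is E
  # choose a state with exactly two passable doors, one to an unvisited cell
  h <- list(state = maze_state(0, 0, "S"), conf = 1L,
            visited = bitwOr(bit(0, 0), bit(0, 1)))
  # facing S at the NW corner: left door (E, to visited (0,1)) and forward
  # (S, to unvisited (1,0)) are open
  expect_equal(efficient_exploration_policy(m, h, params),
               c(left = 0.2, forward = 0.8, right = 0))
  # both passable doors unvisited: beta mass renormalizes to uniform
  h2 <- list(state = maze_state(0, 0, "S"), conf = 1L, visited = bit(0, 0))
  expect_equal(efficient_exploration_policy(m, h2, params),
               c(left = 0.5, forward = 0.5, right = 0))
  # all adjacent cells visited: optimal action starts a shortest open-door
  # path toward the nearest unexplored cell
  vis <- Reduce(bitwOr, c(bit(0, 0), bit(0, 1), bit(1, 0), bit(1, 1),
                          bit(2, 0), bit(2, 1)))
  h3 <- list(state = maze_state(1, 0, "N"), conf = 1L, visited = vis)
  # unvisited cells are in column 2; from (1,0) facing N the passable moves
  # are forward (0,0), right (1,1): (1,1) is 1 step from column 2, (0,0) is 2
  pol <- efficient_exploration_policy(m, h3, params)
  expect_equal(pol[["right"]], 0.8)
  expect_equal(pol[["forward"]], 0.2)
  # everything visited: all passable actions share the mass uniformly
  all_vis <- Reduce(bitwOr, lapply(0:8, function(i) bitwShiftL(1L, i)))
  h4 <- list(state = maze_state(1, 1, "N"), conf = 1L, visited = all_vis)
  expect_equal(unname(efficient_exploration_policy(m, h4, params)),
               rep(1 / 3, 3))
})

test_that("confidence transitions follow the update and backtrack matrices", {
  params <- model_params(p_lh = 0.3, p_hl = 0.6)
  expect_equal(confidence_transition(0, "update", params), c(`0` = 0.7, `1` = 0.3))
  expect_equal(confidence_transition(1, "update", params), c(`0` = 0, `1` = 1))
  expect_equal(confidence_transition(1, "backtrack", params), c(`0` = 0.6, `1` = 0.4))
  expect_equal(confidence_transition(0, "backtrack", params), c(`0` = 1, `1` = 0))
  # the exceptional modes reuse the two matrices
  expect_equal(confidence_transition(1, "action_backtrack", params),
               confidence_transition(1, "backtrack", params))
  expect_equal(confidence_transition(0, "forced_update", params),
               confidence_transition(0, "update", params))
})

test_that("operant modes classify prediction mismatches and revisits", {
  m <- fixture_maze_open3()
  bit <- function(r, c) bitwShiftL(1L, r * 3L + c)
  # prediction mismatch -> backtrack regardless of visitation
  h <- list(state = maze_state(0, 0, "S"), conf = 0L, visited = bit(0, 0))
  # moving forward from (0,0,S) reaches (1,0,S), whose scene has label
  a <- "forward"
  true_next <- scene_of(m, transition(m, h$state, a))
  wrong <- label_to_scene(setdiff(1:7, scene_label(true_next))[1])
  expect_identical(classify_mode(m, h, a, wrong), "backtrack")
  # match + unvisited destination -> update
  expect_identical(classify_mode(m, h, a, true_next), "update")
  # match + visited destination with an unvisited alternative -> action_backtrack
  h2 <- list(state = maze_state(0, 0, "S"), conf = 0L,
             visited = bitwOr(bit(0, 0), bit(1, 0)))
  expect_identical(classify_mode(m, h2, a, true_next), "action_backtrack")
  # match + visited destination but every passable door leads to a visited
  # cell -> forced update
  h3 <- list(state = maze_state(0, 0, "S"), conf = 0L,
             visited = Reduce(bitwOr, c(bit(0, 0), bit(1, 0), bit(0, 1))))
  expect_identical(classify_mode(m, h3, a, true_next), "forced_update")
  # staying in place (closed door) is an update, not a revisit
  h4 <- list(state = maze_state(0, 0, "N"), conf = 0L, visited = bit(0, 0))
  same <- scene_of(m, h4$state)
  expect_identical(classify_mode(m, h4, "forward", same), "update")
})

test_that("one filter step resolves a two-hypothesis ambiguity by Bayes", {
  # fixture B: scene (1,1,1) is shared by exactly two states; stepping
  # forward disambiguates them through the next observation
  m <- fixture_maze_b3()
  cand <- candidate_states(m, scene(TRUE, TRUE, TRUE))
  expect_length(cand, 2L)
  B <- init_belief(m, scene(TRUE, TRUE, TRUE))
  nexts <- vapply(cand, function(s)
    scene_label(scene_of(m, transition(m, s, "forward"))), integer(1))
  expect_true(nexts[1] != nexts[2])  # the move is informative
  st <- step_filter(B, "forward", label_to_scene(nexts[1]), m,
                    default_theta(),
                    history = list(scenes = list(scene(TRUE, TRUE, TRUE),
                                                 label_to_scene(nexts[1])),
                                   actions = "forward"))
  # all surviving update-mode mass sits on the matching state's successor
  upd <- Filter(function(h) h$mode %in% c("update", "forced_update"),
                st$belief$hypotheses)
  states <- unique(vapply(upd, function(h) format(h$state), character(1)))
  expect_identical(states, format(transition(m, cand[[1]], "forward")))
})

test_that("the filter matches exhaustive trajectory enumeration on fixture mazes", {
  set.seed(1)
  cases <- expand.grid(maze = c("open", "b"), seed = 1:4,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    m <- if (cases$maze[i] == "open") fixture_maze_open3() else fixture_maze_b3()
    # open-door actions only: a visibly closed door has zero probability
    # under every hypothesis, which triggers the filter's documented floor
    # (tested separately) rather than Bayes
    walk <- random_walk(m, 6, seed = 400 + cases$seed[i],
                        p_closed_attempt = 0)
    params <- model_params(0.8, 0.75, 0.35, 0.55, 2)
    orc <- oracle_filter(m, walk$scenes, walk$actions, params)
    got <- run_step_filter(m, walk$scenes, walk$actions, params)
    expect_equal(got$pred_probs, orc$pred_probs, tolerance = 1e-10)
    post <- belief_posterior(got$belief)
    expect_setequal(names(post), names(orc$posterior))
    expect_equal(unname(post[names(orc$posterior)]),
                 unname(orc$posterior), tolerance = 1e-10)
    # belief stays normalized throughout
    expect_equal(sum(vapply(got$belief$hypotheses, `[[`, numeric(1), "weight")),
                 1, tolerance = 1e-12)
  }
})

test_that("the compiled filter reproduces the reference filter exactly", {
  m <- fixture_maze_5()
  params <- default_theta()
  log <- quick_log(n_games = 3, seed = 31, m = m, params = params)
  for (variant in c("switching", "forward_only", "efficient_only")) {
    a <- filter_log(log, m, params, variant = variant, engine = "cpp")
    b <- filter_log(log, m, params, variant = variant, engine = "r")
    expect_equal(a$nle, b$nle, tolerance = 1e-10)
    expect_equal(a$actions$predictive_prob, b$actions$predictive_prob,
                 tolerance = 1e-12)
    expect_identical(a$predictions$c_hat, b$predictions$c_hat)
    expect_identical(a$predictions$map_row, b$predictions$map_row)
    expect_identical(a$predictions$pred_scene_label, b$predictions$pred_scene_label)
    expect_equal(as.matrix(a$predictions[, paste0("p", 0:7)]),
                 as.matrix(b$predictions[, paste0("p", 0:7)]),
                 tolerance = 1e-12)
  }
})

test_that("action prediction marginalizes the strategies and returns ties as a set", {
  m <- fixture_maze_open3()
  params <- model_params(alpha = 0.7)
  B <- init_belief(m, scene(TRUE, TRUE, TRUE))  # center cell, 4 orientations
  # single hypothesis: forward wins outright
  B1 <- B; B1$hypotheses <- B1$hypotheses[1]; B1$hypotheses[[1]]$weight <- 1
  expect_identical(predict_action(B1, m, params), "forward")
  # two equal-weight hypotheses with opposing single-door optima: the
  # marginal ties and both actions are returned
  mb <- fixture_maze_b3()
  s_left <- candidate_states(mb, label_to_scene(4))[[1]]   # only left open
  s_right <- candidate_states(mb, label_to_scene(1))[[1]]  # only right open
  B2 <- structure(list(hypotheses = list(
    new_hyp_for_test(s_left, 0.5), new_hyp_for_test(s_right, 0.5)),
    trial_index = 1L), class = "belief_state")
  acts <- predict_action(B2, mb, params)
  expect_setequal(acts, c("left", "right"))
})

test_that("scene prediction pushes the belief through the action", {
  m <- fixture_maze_b3()
  B <- init_belief(m, scene(TRUE, TRUE, TRUE))
  # single hypothesis: point mass
  B1 <- B; B1$hypotheses <- B1$hypotheses[1]; B1$hypotheses[[1]]$weight <- 1
  psd <- predict_scene_dist(B1, "forward", m)
  expect_equal(sum(psd$dist), 1)
  expect_equal(unname(psd$dist[as.character(psd$label)]), 1)
  # three weighted hypotheses: the mixture matches the hand-built sum
  cand <- candidate_states(m, scene(TRUE, FALSE, TRUE))
  B3 <- init_belief(m, scene(TRUE, FALSE, TRUE))
  B3$hypotheses <- B3$hypotheses[1:3]
  w <- c(0.5, 0.3, 0.2)
  for (i in 1:3) B3$hypotheses[[i]]$weight <- w[i]
  psd3 <- predict_scene_dist(B3, "right", m)
  manual <- setNames(numeric(8), as.character(0:7))
  for (i in 1:3) {
    lab <- scene_label(scene_of(m, transition(m, cand[[i]], "right")))
    manual[as.character(lab)] <- manual[as.character(lab)] + w[i]
  }
  expect_equal(psd3$dist, manual)
  expect_equal(sum(psd3$dist), 1)
})

test_that("state-confidence estimation uses the maximal-marginal states and breaks ties low", {
  m <- fixture_maze_b3()
  mk <- function(states, confs, ws) {
    structure(list(hypotheses = Map(function(s, cc, w) {
      h <- new_hyp_for_test(s, w); h$conf <- as.integer(cc); h
    }, states, confs, ws), trial_index = 1L), class = "belief_state")
  }
  s1 <- maze_state(0, 0, "E"); s2 <- maze_state(1, 2, "S")
  # all mass at low confidence
  expect_identical(estimate_state_confidence(mk(list(s1, s2), c(0, 0), c(0.6, 0.4))), 0L)
  # single state with P(c=1) = 0.6 > P(c=0) = 0.4
  expect_identical(estimate_state_confidence(mk(list(s1, s1), c(1, 0), c(0.6, 0.4))), 1L)
  # exact tie goes to low
  expect_identical(estimate_state_confidence(mk(list(s1, s1), c(1, 0), c(0.5, 0.5))), 0L)
  # the c=1 mass must sit on a maximal-marginal state to count
  expect_identical(estimate_state_confidence(
    mk(list(s1, s2, s2), c(1, 0, 1), c(0.2, 0.45, 0.35))), 0L)
})

test_that("with p_lh = 0 the switching filter reduces to the forward-only variant", {
  m <- fixture_maze_5()
  log <- quick_log(n_games = 3, seed = 13, m = m)
  p0 <- model_params(0.85, 0.6, 0, 0.5, 2)
  expect_equal(negative_log_evidence(log, m, p0, "switching"),
               negative_log_evidence(log, m, p0, "forward_only"),
               tolerance = 1e-10)
})

test_that("an action no hypothesis allows hits the likelihood floor, not an error", {
  m <- fixture_maze_b3()
  s <- candidate_states(m, label_to_scene(1))[[1]]  # only the right door open
  B <- structure(list(hypotheses = list(new_hyp_for_test(s, 1)),
                      trial_index = 1L), class = "belief_state")
  st <- step_filter(B, "left", scene_of(m, s), m, default_theta(),
                    history = list(scenes = list(scene_of(m, s)),
                                   actions = character(0)))
  expect_true(st$zero_guard)
  expect_equal(st$predictive_prob, 1e-10)
  expect_equal(sum(vapply(st$belief$hypotheses, `[[`, numeric(1), "weight")), 1)
})

test_that("filter traces are deterministic for identical inputs", {
  m <- fixture_maze_5()
  log <- quick_log(n_games = 2, seed = 5, m = m)
  a <- filter_log(log, m, default_theta())
  b <- filter_log(log, m, default_theta())
  expect_identical(a, b)
})
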