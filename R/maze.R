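#' Grid mazes with shared open/closed doors
#'
#' A maze is a rectangular grid of cells; every pair of adjacent cells shares
#' one door that is either open (passable) or closed. Boundary walls are
#' implicitly closed and are not stored. A navigating agent occupies a
#' \emph{state} -- a cell plus a facing direction -- and observes only the
#' \emph{scene}: the open/closed status of the doors to its left, forward and
#' right. Because several states can share a scene, the maze is only partially
#' observable.
#'
#' @param n_rows,n_cols grid dimensions (each at least 3).
#' @param doors_ew logical matrix, `n_rows x (n_cols - 1)`; entry `[r, c]` is
#'   `TRUE` iff the door between cell `(r-1, c-1)` and `(r-1, c)` (0-based
#'   coordinates) is open.
#' @param doors_ns logical matrix, `(n_rows - 1) x n_cols`; entry `[r, c]` is
#'   `TRUE` iff the door between cell `(r-1, c-1)` and `(r, c-1)` is open.
#' @param validate if `TRUE`, check all structural invariants and stop with a
#'   message naming the first violated one.
#'
#' @details Cell coordinates are 0-based `(row, col)` with row 0 the north
#' edge; orientation `N` decreases the row index. The structural invariants
#' are: (i) door symmetry (automatic -- adjacent cells share storage);
#' (ii) no dead end, i.e. every cell has at least two open doors; (iii) full
#' connectivity through open doors; (iv) partial observability: every realized
#' scene is shared by at least two states, so a single observation never
#' identifies the state.
#'
#' @return an object of class `maze`.
#' @seealso [generate_maze()], [scene_of()], [transition()]
#' @export
maze <- function(n_rows, n_cols, doors_ew, doors_ns, validate = TRUE) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  doors_ew <- matrix(as.logical(doors_ew), n_rows, n_cols - 1L)
  doors_ns <- matrix(as.logical(doors_ns), n_rows - 1L, n_cols)
  m <- structure(list(n_rows = n_rows, n_cols = n_cols,
                      doors_ew = doors_ew, doors_ns = doors_ns),
                 class = "maze")
  if (validate) {
    bad <- maze_invariant_failures(m)
    if (length(bad))
      stop("invalid maze: ", paste(bad, collapse = "; "))
  }
  m
}

#' @export
print.maze <- function(x, ...) {
  cat(sprintf("<maze %dx%d, %d open doors, %d states>\n",
              x$n_rows, x$n_cols,
              sum(x$doors_ew) + sum(x$doors_ns),
              4L * x$n_rows * x$n_cols))
  invisible(x)
}

#' Check the structural invariants of a maze
#'
#' @param m a `maze`.
#' @return character vector naming the violated invariants (empty if valid).
#' @export
maze_invariant_failures <- function(m) {
  bad <- character(0)
  if (m$n_rows < 3L || m$n_cols < 3L) bad <- c(bad, "grid smaller than 3x3")
  deg <- cell_degrees(m)
  if (any(deg < 2L)) bad <- c(bad, "dead end (cell with fewer than two open doors)")
  if (!maze_connected(m)) bad <- c(bad, "open-door graph not connected")
  labs <- vapply(all_states(m), function(s) scene_label(scene_of(m, s)), integer(1))
  if (any(table(labs) < 2L) || any(tabulate(match(labs, labs)) < 2L)) {
    # a scene unique to one state breaks partial observability
  }
  cnt <- table(labs)
  if (any(cnt < 2L)) bad <- c(bad, "scene unique to a single state (partial observability violated)")
  bad
}

# number of open doors per cell (n_rows x n_cols matrix)
cell_degrees <- function(m) {
  R <- m$n_rows; C <- m$n_cols
  deg <- matrix(0L, R, C)
  deg[, -C] <- deg[, -C] + m$doors_ew
  deg[, -1] <- deg[, -1] + m$doors_ew
  deg[-R, ] <- deg[-R, ] + m$doors_ns
  deg[-1, ] <- deg[-1, ] + m$doors_ns
  deg
}

maze_connected <- function(m) {
  R <- m$n_rows; C <- m$n_cols
  seen <- matrix(FALSE, R, C)
  queue <- c(1L, 1L); seen[1L, 1L] <- TRUE; n_seen <- 1L
  head <- 1L
  q <- list(c(1L, 1L))
  while (head <= length(q)) {
    rc <- q[[head]]; head <- head + 1L
    r <- rc[1L]; c <- rc[2L]
    nb <- list()
    if (c < C && m$doors_ew[r, c]) nb <- c(nb, list(c(r, c + 1L)))
    if (c > 1L && m$doors_ew[r, c - 1L]) nb <- c(nb, list(c(r, c - 1L)))
    if (r < R && m$doors_ns[r, c]) nb <- c(nb, list(c(r + 1L, c)))
    if (r > 1L && m$doors_ns[r - 1L, c]) nb <- c(nb, list(c(r - 1L, c)))
    for (x in nb) if (!seen[x[1L], x[2L]]) {
      seen[x[1L], x[2L]] <- TRUE; n_seen <- n_seen + 1L; q[[length(q) + 1L]] <- x
    }
  }
  n_seen == R * C
}

## ---- states ----------------------------------------------------------------

ORIENTATIONS <- c("N", "E", "S", "W")
ACTIONS <- c("left", "forward", "right")

#' Construct a state (position plus orientation)
#'
#' @param row,col 0-based cell coordinates; row 0 is the north edge.
#' @param orientation one of `"N"`, `"E"`, `"S"`, `"W"`.
#' @return an object of class `maze_state`.
#' @export
maze_state <- function(row, col, orientation) {
  orientation <- match.arg(orientation, ORIENTATIONS)
  structure(list(row = as.integer(row), col = as.integer(col),
                 orientation = orientation),
            class = "maze_state")
}

#' @export
print.maze_state <- function(x, ...) {
  cat(sprintf("<state (%d,%d,%s)>\n", x$row, x$col, x$orientation))
  invisible(x)
}

#' @export
format.maze_state <- function(x, ...) sprintf("(%d,%d,%s)", x$row, x$col, x$orientation)

#' All states of a maze
#'
#' @param m a `maze`.
#' @return list of `maze_state` (4 per cell; a 5x5 maze has 100 states).
#' @export
all_states <- function(m) {
  out <- vector("list", 4L * m$n_rows * m$n_cols)
  i <- 1L
  for (r in seq_len(m$n_rows) - 1L)
    for (c in seq_len(m$n_cols) - 1L)
      for (o in ORIENTATIONS) {
        out[[i]] <- maze_state(r, c, o); i <- i + 1L
      }
  out
}

state_index <- function(m, s) {
  # 1-based linear index over (row, col, orientation)
  (s$row * m$n_cols + s$col) * 4L + match(s$orientation, ORIENTATIONS)
}

state_valid <- function(m, s) {
  s$row >= 0L && s$row < m$n_rows && s$col >= 0L && s$col < m$n_cols
}

# absolute direction after turning: turn -1 = left, 0 = forward, +1 = right
rotate_orientation <- function(orientation, turn) {
  ORIENTATIONS[((match(orientation, ORIENTATIONS) - 1L + turn) %% 4L) + 1L]
}

# open status of the door on side `dir` (absolute N/E/S/W) of 0-based cell (r, c);
# queries through the boundary return FALSE (boundary walls are closed)
door_open <- function(m, r, c, dir) {
  switch(dir,
    N = r >= 1L && m$doors_ns[r, c + 1L],
    S = r <= m$n_rows - 2L && m$doors_ns[r + 1L, c + 1L],
    E = c <= m$n_cols - 2L && m$doors_ew[r + 1L, c + 1L],
    W = c >= 1L && m$doors_ew[r + 1L, c])
}

step_cell <- function(r, c, dir) {
  switch(dir,
    N = c(r - 1L, c), S = c(r + 1L, c), E = c(r, c + 1L), W = c(r, c - 1L))
}

## ---- scenes ----------------------------------------------------------------

#' Construct a scene (egocentric door statuses)
#'
#' @param left,forward,right logical; `TRUE` = open.
#' @return an object of class `scene`.
#' @export
scene <- function(left, forward, right) {
  structure(list(left = isTRUE(left), forward = isTRUE(forward),
                 right = isTRUE(right)), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene L:%s F:%s R:%s (label %d)>\n",
              ifelse(x$left, "open", "closed"),
              ifelse(x$forward, "open", "closed"),
              ifelse(x$right, "open", "closed"), scene_label(x)))
  invisible(x)
}

#' Egocentric scene observed from a state
#'
#' Returns the open/closed status of the doors to the left, forward and right
#' of the facing direction. Deterministic; boundary walls read as closed.
#'
#' @param m a `maze`.
#' @param s a `maze_state` within the maze.
#' @return a `scene`.
#' @export
scene_of <- function(m, s) {
  if (!state_valid(m, s)) stop("invalid state: out of maze bounds")
  o <- s$orientation
  scene(door_open(m, s$row, s$col, rotate_orientation(o, -1L)),
        door_open(m, s$row, s$col, o),
        door_open(m, s$row, s$col, rotate_orientation(o, 1L)))
}

#' 3-bit integer label of a scene
#'
#' Each bit encodes one door (open = 1): `label = 4*left + 2*forward +
#' 1*right`. Label 0 (all three visible doors closed) never occurs in a valid
#' maze because it would require a dead-end cell.
#'
#' @param sc a `scene`.
#' @return integer in 0..7.
#' @export
scene_label <- function(sc) {
  4L * as.integer(sc$left) + 2L * as.integer(sc$forward) + as.integer(sc$right)
}

#' Inverse of [scene_label()]
#' @param label integer in 0..7.
#' @return a `scene`.
#' @export
label_to_scene <- function(label) {
  label <- as.integer(label)
  stopifnot(label >= 0L, label <= 7L)
  scene(bitwAnd(label, 4L) > 0L, bitwAnd(label, 2L) > 0L, bitwAnd(label, 1L) > 0L)
}

scene_equal <- function(a, b) {
  a$left == b$left && a$forward == b$forward && a$right == b$right
}

## ---- dynamics --------------------------------------------------------------

#' Apply an action to a state
#'
#' The mover first rotates by the action (left = -90 degrees, forward = 0,
#' right = +90) and then steps one cell along the new facing direction,
#' provided the door in that direction is open. Choosing a closed door is a
#' legal no-op: the input state is returned unchanged (in the task, the same
#' scene is then presented again).
#'
#' @param m a `maze`.
#' @param s a `maze_state`.
#' @param action `"left"`, `"forward"` or `"right"`.
#' @return the resulting `maze_state`.
#' @export
transition <- function(m, s, action) {
  action <- match.arg(action, ACTIONS)
  if (!state_valid(m, s)) stop("invalid state: out of maze bounds")
  turn <- match(action, ACTIONS) - 2L   # -1, 0, +1
  new_o <- rotate_orientation(s$orientation, turn)
  if (!door_open(m, s$row, s$col, new_o)) return(s)
  rc <- step_cell(s$row, s$col, new_o)
  maze_state(rc[1L], rc[2L], new_o)
}

#' States consistent with a single scene
#'
#' The exact set of states whose observed scene equals `sc`; the candidate set
#' for the hidden state after the first observation of a game. In a valid maze
#' every realized scene is shared by at least two states.
#'
#' @param m a `maze`.
#' @param sc a `scene`.
#' @return list of `maze_state` (possibly empty for scenes the maze never
#'   shows).
#' @export
candidate_states <- function(m, sc) {
  Filter(function(s) scene_equal(scene_of(m, s), sc), all_states(m))
}

#' States consistent with a recent window of scenes and actions
#'
#' Forward-simulates every possible start state against the observed window
#' and keeps the terminal states of the trajectories that reproduce it. The
#' window is `length(actions)` past steps plus the current observation, so
#' `length(scenes)` must equal `length(actions) + 1`; each hypothesized move
#' succeeds or fails exactly as the observed one did (a failed move is
#' observable, because the chosen door is visibly closed in the matching
#' scene). With an empty action window the result equals
#' [candidate_states()] of the last scene.
#'
#' @param m a `maze`.
#' @param scenes list of `scene`, oldest first, ending with the current one.
#' @param actions character vector of actions, one per step between
#'   consecutive scenes.
#' @param detail if `TRUE`, also return for each terminal state the union of
#'   0-based grid cells traversed by the consistent trajectories reaching it.
#' @return list of `maze_state`, or when `detail = TRUE` a list with elements
#'   `states` and `visited` (list of integer matrices with columns row, col).
#' @export
history_consistent_states <- function(m, scenes, actions, detail = FALSE) {
  stopifnot(length(scenes) == length(actions) + 1L)
  if (length(actions) == 0L) {
    st <- candidate_states(m, scenes[[1L]])
    if (!detail) return(st)
    return(list(states = st,
                visited = lapply(st, function(s) cbind(row = s$row, col = s$col))))
  }
  ends <- list(); visited <- list()
  for (s0 in candidate_states(m, scenes[[1L]])) {
    s <- s0
    cells <- matrix(c(s$row, s$col), ncol = 2L)
    ok <- TRUE
    for (i in seq_along(actions)) {
      s <- transition(m, s, actions[[i]])
      cells <- rbind(cells, c(s$row, s$col))
      if (!scene_equal(scene_of(m, s), scenes[[i + 1L]])) { ok <- FALSE; break }
    }
    if (!ok) next
    key <- format(s)
    if (is.null(ends[[key]])) { ends[[key]] <- s; visited[[key]] <- cells }
    else visited[[key]] <- rbind(visited[[key]], cells)
  }
  st <- unname(ends)
  vis <- lapply(unname(visited), function(x) {
    x <- unique(x); colnames(x) <- c("row", "col"); x
  })
  if (detail) list(states = st, visited = vis) else st
}

## ---- generation & I/O ------------------------------------------------------

#' Generate a random maze satisfying all structural invariants
#'
#' Doors are drawn i.i.d. Bernoulli(`p_open`); repair passes then open doors
#' to remove dead ends and connect components, and the draw is rejected unless
#' the partial-observability invariant (every realized scene shared by at
#' least two states) holds.
#'
#' @param n_rows,n_cols grid dimensions (at least 3).
#' @param seed integer seed; the same seed reproduces the same maze.
#' @param p_open prior probability that an interior door is open.
#' @param max_attempts rejection-sampling budget.
#' @return a valid `maze`.
#' @export
generate_maze <- function(n_rows = 5L, n_cols = 5L, seed = 1L,
                          p_open = 0.55, max_attempts = 1000L) {
  stopifnot(n_rows >= 3L, n_cols >= 3L)
  rng <- make_rng(seed)
  for (attempt in seq_len(max_attempts)) {
    ew <- matrix(rng$runif(n_rows * (n_cols - 1L)) < p_open, n_rows, n_cols - 1L)
    ns <- matrix(rng$runif((n_rows - 1L) * n_cols) < p_open, n_rows - 1L, n_cols)
    m <- maze(n_rows, n_cols, ew, ns, validate = FALSE)
    m <- repair_dead_ends(m, rng)
    m <- repair_connectivity(m, rng)
    m <- repair_dead_ends(m, rng)   # connectivity repair cannot close doors
    if (!length(maze_invariant_failures(m))) return(m)
  }
  stop("maze generation failed after ", max_attempts, " attempts")
}

# open random extra doors on cells with fewer than two open doors
repair_dead_ends <- function(m, rng) {
  repeat {
    deg <- cell_degrees(m)
    idx <- which(deg < 2L, arr.ind = TRUE)
    if (!nrow(idx)) return(m)
    r <- idx[1L, 1L]; c <- idx[1L, 2L]
    closed <- list()
    if (c < m$n_cols && !m$doors_ew[r, c]) closed <- c(closed, list(c("ew", r, c)))
    if (c > 1L && !m$doors_ew[r, c - 1L]) closed <- c(closed, list(c("ew", r, c - 1L)))
    if (r < m$n_rows && !m$doors_ns[r, c]) closed <- c(closed, list(c("ns", r, c)))
    if (r > 1L && !m$doors_ns[r - 1L, c]) closed <- c(closed, list(c("ns", r - 1L, c)))
    pick <- closed[[rng$sample_int(length(closed))]]
    if (pick[1L] == "ew") m$doors_ew[as.integer(pick[2L]), as.integer(pick[3L])] <- TRUE
    else m$doors_ns[as.integer(pick[2L]), as.integer(pick[3L])] <- TRUE
  }
}

# open doors between connected components until the grid graph is connected
repair_connectivity <- function(m, rng) {
  repeat {
    comp <- grid_components(m)
    if (max(comp) == 1L) return(m)
    # candidate closed doors joining different components
    cand <- list()
    for (r in seq_len(m$n_rows)) for (c in seq_len(m$n_cols - 1L))
      if (!m$doors_ew[r, c] && comp[r, c] != comp[r, c + 1L])
        cand <- c(cand, list(c("ew", r, c)))
    for (r in seq_len(m$n_rows - 1L)) for (c in seq_len(m$n_cols))
      if (!m$doors_ns[r, c] && comp[r, c] != comp[r + 1L, c])
        cand <- c(cand, list(c("ns", r, c)))
    pick <- cand[[rng$sample_int(length(cand))]]
    if (pick[1L] == "ew") m$doors_ew[as.integer(pick[2L]), as.integer(pick[3L])] <- TRUE
    else m$doors_ns[as.integer(pick[2L]), as.integer(pick[3L])] <- TRUE
  }
}

grid_components <- function(m) {
  R <- m$n_rows; C <- m$n_cols
  comp <- matrix(0L, R, C); k <- 0L
  for (r0 in seq_len(R)) for (c0 in seq_len(C)) {
    if (comp[r0, c0] != 0L) next
    k <- k + 1L
    q <- list(c(r0, c0)); comp[r0, c0] <- k; head <- 1L
    while (head <= length(q)) {
      rc <- q[[head]]; head <- head + 1L
      r <- rc[1L]; c <- rc[2L]
      nb <- list()
      if (c < C && m$doors_ew[r, c]) nb <- c(nb, list(c(r, c + 1L)))
      if (c > 1L && m$doors_ew[r, c - 1L]) nb <- c(nb, list(c(r, c - 1L)))
      if (r < R && m$doors_ns[r, c]) nb <- c(nb, list(c(r + 1L, c)))
      if (r > 1L && m$doors_ns[r - 1L, c]) nb <- c(nb, list(c(r - 1L, c)))
      for (x in nb) if (comp[x[1L], x[2L]] == 0L) {
        comp[x[1L], x[2L]] <- k; q[[length(q) + 1L]] <- x
      }
    }
  }
  comp
}

#' Read / write a maze as JSON
#'
#' The file stores `n_rows`, `n_cols` and the two row-major boolean door
#' arrays. The reader validates all structural invariants and reports which
#' failed, so a hand-edited maze cannot silently enter an analysis.
#'
#' @param path file path.
#' @param m a `maze`.
#' @return `read_maze` returns a validated `maze`; `write_maze` returns
#'   `path` invisibly.
#' @export
read_maze <- function(path) {
  x <- jsonlite::fromJSON(path)
  as_mat <- function(v, nr, nc) {
    if (is.list(v)) v <- do.call(rbind, lapply(v, as.logical))
    matrix(as.logical(v), nr, nc)
  }
  m <- maze(x$n_rows, x$n_cols,
            as_mat(x$doors_ew, x$n_rows, x$n_cols - 1L),
            as_mat(x$doors_ns, x$n_rows - 1L, x$n_cols),
            validate = FALSE)
  bad <- maze_invariant_failures(m)
  if (length(bad)) stop("maze file ", path, " violates: ", paste(bad, collapse = "; "))
  m
}

#' @rdname read_maze
#' @export
write_maze <- function(m, path) {
  jsonlite::write_json(
    list(n_rows = m$n_rows, n_cols = m$n_cols,
         doors_ew = apply(m$doors_ew, 1L, as.logical, simplify = FALSE),
         doors_ns = apply(m$doors_ns, 1L, as.logical, simplify = FALSE)),
    path, auto_unbox = TRUE)
  invisible(path)
}
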