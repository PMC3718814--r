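#' Rake-and-pellet gridworld environment
#'
#' Deterministic MDP of the 7x7 rake task. A pellet sits on a 7-deep table
#' (depth 1 = front edge nearest the agent, 7 = back edge); a T-shaped rake
#' whose 3-cell crossbar can push or pull the pellet one cell per move when
#' the crossbar sweeps into the pellet's cell. The state is 3-dimensional:
#' pellet depth (1..7), lateral rake-pellet offset `rake_dx` (-6..6) and
#' depth offset `rake_dy` (-6..6, negative = rake in front of the pellet),
#' giving 7 x 13 x 13 = 1183 states. Pulling the pellet off the front edge
#' ends the trial with reward +1; pushing it off the back edge ends it with
#' reward -0.2.
#'
#' The rake starts behind the pellet (default offset `(0, +3)`). The small
#' default per-step penalty makes endless wandering strictly worse than
#' finishing the trial; without it an agent whose early successes were
#' misreported as penalties can settle into indefinite zero-reward
#' loitering, since an untouched region of the workspace then looks no
#' worse than either terminal.
#'
#' @param reward_success Terminal reward for the pellet leaving the front
#'   edge (default +1).
#' @param reward_failure Terminal reward for the pellet leaving the back
#'   edge (default -0.2).
#' @param start_dx,start_dy Rake start offsets relative to the pellet.
#' @param step_penalty Per-step reward (default -0.005; small negative
#'   values encourage faster solutions and rule out loitering).
#' @return A list of class `rake_env`.
#' @examples
#' env <- rake_env()
#' s <- rake_reset(env)
#' rake_step(s, "left", env)
#' @export
rake_env <- function(reward_success = 1.0, reward_failure = -0.2,
                     start_dx = 0L, start_dy = 3L, step_penalty = -0.005) {
  if (abs(start_dx) > 6 || abs(start_dy) > 6) {
    stop("start offsets must lie within [-6, 6]")
  }
  structure(list(reward_success = reward_success,
                 reward_failure = reward_failure,
                 start_dx = as.integer(start_dx),
                 start_dy = as.integer(start_dy),
                 step_penalty = step_penalty),
            class = "rake_env")
}

#' The four rake actions
#'
#' `left`/`right` move the rake laterally (never displacing the pellet);
#' `pull` moves it one cell toward the front edge, `push` one cell toward
#' the back edge.
#'
#' @return Character vector of the 4 action names, in canonical order.
#' @export
rake_actions <- function() c("left", "right", "pull", "push")

#' Enumerate the full state space
#'
#' Canonical ordering: pellet depth major, then lateral offset, then depth
#' offset. `index` is the 1-based position in this ordering and round-trips
#' with [state_index()] / [state_from_index()].
#'
#' @return A tibble with 1183 rows: `index`, `pellet_depth`, `rake_dx`,
#'   `rake_dy`.
#' @export
enumerate_states <- function() {
  grid <- expand.grid(rake_dy = -6:6, rake_dx = -6:6, pellet_depth = 1:7)
  out <- tibble::tibble(
    index = seq_len(nrow(grid)),
    pellet_depth = as.integer(grid$pellet_depth),
    rake_dx = as.integer(grid$rake_dx),
    rake_dy = as.integer(grid$rake_dy))
  out
}

#' Map a state to its canonical index (and back)
#'
#' @param pellet_depth,rake_dx,rake_dy State components (vectorized).
#' @return `state_index()`: integer index in 1..1183.
#' @export
state_index <- function(pellet_depth, rake_dx, rake_dy) {
  stopifnot(all(pellet_depth >= 1 & pellet_depth <= 7),
            all(abs(rake_dx) <= 6), all(abs(rake_dy) <= 6))
  as.integer((pellet_depth - 1) * 169 + (rake_dx + 6) * 13 +
               (rake_dy + 6) + 1)
}

#' @rdname state_index
#' @param index Integer index in 1..1183.
#' @return `state_from_index()`: a tibble with the three state components.
#' @export
state_from_index <- function(index) {
  stopifnot(all(index >= 1 & index <= 1183))
  i <- as.integer(index) - 1L
  tibble::tibble(pellet_depth = i %/% 169L + 1L,
                 rake_dx = (i %/% 13L) %% 13L - 6L,
                 rake_dy = i %% 13L - 6L)
}

#' Reset the environment to the trial start state
#'
#' The pellet is initialized to the center of the grid (depth 4) and the
#' rake to its configured start offset. Deterministic: every trial starts
#' identically.
#'
#' @param env A [rake_env()].
#' @return Named integer vector `(pellet_depth, rake_dx, rake_dy)`.
#' @export
rake_reset <- function(env = rake_env()) {
  c(pellet_depth = 4L, rake_dx = env$start_dx, rake_dy = env$start_dy)
}

#' Advance the environment one rake move
#'
#' Lateral moves change `rake_dx` only. Depth moves change `rake_dy`,
#' except when the crossbar (3 cells wide, so `|rake_dx| <= 1`) would
#' arrive exactly at the pellet's depth: then the pellet is swept one cell
#' in the move direction and the offset is preserved. A move that would
#' push either offset beyond +/-6 is a no-op (the rake is clamped at the
#' edge of its workspace). The pellet leaving depth 1 toward the agent
#' terminates with `reward_success`; leaving depth 7 backward terminates
#' with `reward_failure`.
#'
#' @param state Named integer vector from [rake_reset()] or
#'   [state_from_index()].
#' @param action One of [rake_actions()] (name or index 1..4).
#' @param env A [rake_env()].
#' @return List with `state` (next state, or `NULL` if terminal), `reward`
#'   (the true task reward), `terminal` (logical).
#' @export
rake_step <- function(state, action, env = rake_env()) {
  if (is.character(action)) action <- match(action, rake_actions())
  if (is.na(action) || !action %in% 1:4) stop("invalid action")
  pd <- as.integer(state[["pellet_depth"]])
  dx <- as.integer(state[["rake_dx"]])
  dy <- as.integer(state[["rake_dy"]])
  if (pd < 1 || pd > 7 || abs(dx) > 6 || abs(dy) > 6) stop("invalid state")
  r <- env$step_penalty
  if (action <= 2) {                       # lateral: pellet never moves
    dx2 <- dx + if (action == 1) -1L else 1L
    if (abs(dx2) <= 6) dx <- dx2           # else clamped no-op
  } else {
    d <- if (action == 3) -1L else 1L      # pull toward front / push back
    if (abs(dx) <= 1 && dy + d == 0L) {    # crossbar sweeps into the pellet
      pd <- pd + d
      if (pd < 1L) {
        return(list(state = NULL, reward = env$reward_success,
                    terminal = TRUE))
      }
      if (pd > 7L) {
        return(list(state = NULL, reward = env$reward_failure,
                    terminal = TRUE))
      }
    } else {
      dy2 <- dy + d
      if (abs(dy2) <= 6) dy <- dy2         # else clamped no-op
    }
  }
  list(state = c(pellet_depth = pd, rake_dx = dx, rake_dy = dy),
       reward = r, terminal = FALSE)
}
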