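#' SARSA(lambda) agent parameters
#'
#' @param epsilon Exploration probability of the epsilon-greedy policy.
#' @param lambda_trace Eligibility-trace decay in `[0, 1]`.
#' @param gamma Discount factor in `(0, 1]`.
#' @param alpha0 Initial learning rate; annealed per (state, action) as
#'   `alpha0 / (1 + visits)` (see [anneal_alpha()]).
#' @param trace_kind `"replacing"` (default) or `"accumulating"`.
#' @param q_init Initial Q value for every (state, action) pair (default
#'   0; positive values give optimistic initialization).
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(epsilon = 0.05, lambda_trace = 0.9, gamma = 0.95,
                         alpha0 = 0.5, q_init = 0.0,
                         trace_kind = c("replacing", "accumulating")) {
  trace_kind <- match.arg(trace_kind)
  stopifnot(epsilon >= 0, epsilon <= 1, lambda_trace >= 0, lambda_trace <= 1,
            gamma > 0, gamma <= 1, alpha0 > 0, is.finite(q_init))
  structure(list(epsilon = epsilon, lambda_trace = lambda_trace,
                 gamma = gamma, alpha0 = alpha0, q_init = q_init,
                 trace_kind = trace_kind),
            class = "agent_params")
}

#' Initialize an empty tabular value function
#'
#' Q-values and eligibility traces start at zero; visit counts at zero.
#'
#' @param n_states,n_actions Table dimensions (1183 x 4 for the rake task).
#' @param q_init Initial value for every entry (see [agent_params()]).
#' @return A list of class `q_table` with matrices `q`, `trace`, `visits`.
#' @export
q_table <- function(n_states = 1183, n_actions = 4, q_init = 0) {
  z <- matrix(0, n_states, n_actions)
  structure(list(q = z + q_init, trace = z,
                 visits = matrix(0L, n_states, n_actions)),
            class = "q_table")
}

#' Annealed per-(state, action) learning rate
#'
#' `alpha0 / (1 + visits)`: strictly decreasing in the visit count, so each
#' pair's value estimate becomes a running average over its reward history.
#' This averaging is what makes the learner robust to a stochastically
#' misclassified reward signal.
#'
#' @param visit_count Non-negative visit count(s).
#' @param alpha0 Initial learning rate.
#' @return Learning rate(s).
#' @export
anneal_alpha <- function(visit_count, alpha0 = 0.5) {
  stopifnot(all(visit_count >= 0))
  alpha0 / (1 + visit_count)
}

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` an action of maximal value is chosen
#' (ties broken uniformly at random); otherwise an action is drawn
#' uniformly from the non-maximal actions (or from all actions when every
#' value is maximal).
#'
#' @param q A `q_table`.
#' @param state_idx State index (1..nrow).
#' @param params An [agent_params()].
#' @return Integer action index.
#' @export
select_action <- function(q, state_idx, params = agent_params()) {
  row <- q$q[state_idx, ]
  best <- which(row == max(row))
  if (runif(1) >= params$epsilon) {
    if (length(best) == 1) best else
      best[floor(runif(1) * length(best)) + 1]
  } else {
    others <- setdiff(seq_along(row), best)
    if (length(others) == 0) others <- seq_along(row)
    others[floor(runif(1) * length(others)) + 1]
  }
}

#' One SARSA(lambda) update
#'
#' Applies the on-policy temporal-difference update for a transition
#' `(s, a, r, s', a')`: the TD error is
#' `delta = r + gamma * Q(s', a') - Q(s, a)` (with `Q(s', a') = 0` at a
#' terminal `s'`), the eligibility trace at `(s, a)` is set to 1 (replacing
#' traces) or incremented (accumulating), every table entry receives
#' `alpha(u) * delta * trace(u)` with its *own* annealed learning rate
#' `alpha(u) = alpha0 / (1 + visits(u))`, and all traces then decay by
#' `gamma * lambda`. The visit count of `(s, a)` is incremented after the
#' update, so a pair's first update uses `alpha0`. Per-pair annealing makes
#' each entry a running average over the rewards credited to it, which is
#' what absorbs a stochastically misclassified reward signal.
#'
#' @param q A `q_table`.
#' @param s,a Current state index and action index.
#' @param r Delivered reward.
#' @param s2,a2 Next state and action indices (ignored when `terminal`).
#' @param terminal Logical; `TRUE` when `s'` ends the trial.
#' @param params An [agent_params()].
#' @return The updated `q_table`.
#' @export
sarsa_update <- function(q, s, a, r, s2, a2, terminal = FALSE,
                         params = agent_params()) {
  target <- if (terminal) 0 else q$q[s2, a2]
  delta <- r + params$gamma * target - q$q[s, a]
  if (params$trace_kind == "replacing") {
    q$trace[s, a] <- 1
  } else {
    q$trace[s, a] <- q$trace[s, a] + 1
  }
  q$q <- q$q + anneal_alpha(q$visits, params$alpha0) * delta * q$trace
  q$trace <- q$trace * params$gamma * params$lambda_trace
  q$visits[s, a] <- q$visits[s, a] + 1L
  q
}

#' Run one trial (episode) of the rake task with SARSA(lambda) learning
#'
#' Runs the environment from reset to a terminal state (or the step cap),
#' selecting actions epsilon-greedily and applying [sarsa_update()] after
#' each step. At the terminal step the *delivered* reward comes from the
#' noisy reward channel, which reports the correct outcome class with
#' probability `channel$accuracy`; the true outcome is logged separately.
#' Eligibility traces are cleared at the start of the episode. Episodes
#' hitting `step_cap` are truncated with no terminal reward and flagged.
#'
#' @param env A [rake_env()].
#' @param q A `q_table` (updated copy is returned).
#' @param params An [agent_params()].
#' @param channel A [reward_channel()].
#' @param step_cap Maximum steps per episode (default 1000).
#' @return List with `q` (updated table) and `record`, a one-row tibble:
#'   `steps`, `true_success`, `true_reward`, `delivered_reward`,
#'   `truncated`.
#' @export
run_episode <- function(env, q, params = agent_params(),
                        channel = reward_channel(1.0), step_cap = 1000) {
  q$trace[] <- 0
  s_vec <- rake_reset(env)
  s <- state_index(s_vec[1], s_vec[2], s_vec[3])
  a <- select_action(q, s, params)
  steps <- 0L
  repeat {
    out <- rake_step(s_vec, a, env)
    steps <- steps + 1L
    if (out$terminal) {
      success <- out$reward == env$reward_success
      delivered <- flip_reward(if (success) "success" else "failure", channel)
      q <- sarsa_update(q, s, a, delivered, s, a, terminal = TRUE,
                        params = params)
      return(list(q = q, record = tibble::tibble(
        steps = steps, true_success = success, true_reward = out$reward,
        delivered_reward = delivered, truncated = FALSE)))
    }
    s2_vec <- out$state
    s2 <- state_index(s2_vec[1], s2_vec[2], s2_vec[3])
    a2 <- select_action(q, s2, params)
    q <- sarsa_update(q, s, a, out$reward, s2, a2, params = params)
    s_vec <- s2_vec; s <- s2; a <- a2
    if (steps >= step_cap) {
      return(list(q = q, record = tibble::tibble(
        steps = steps, true_success = FALSE, true_reward = 0,
        delivered_reward = 0, truncated = TRUE)))
    }
  }
}

#' Train a SARSA(lambda) agent on the rake task
#'
#' Runs the agent for a fixed budget of environment steps (trials restart
#' from reset at every terminal state), delivering terminal rewards through
#' a noisy reward channel of the given accuracy. The heavy loop runs in
#' compiled code; pass `log_transitions = TRUE` to additionally record
#' every `(s, a, r, s', a')` transition (used for validating the compiled
#' loop against [sarsa_update()]).
#'
#' @param n_steps Total environment steps (the training budget).
#' @param accuracy Reward-channel accuracy in `[0.5, 1]`.
#' @param params An [agent_params()].
#' @param env A [rake_env()].
#' @param seed Integer seed.
#' @param step_cap Per-episode step cap.
#' @param log_transitions Log per-step transitions (memory-heavy).
#' @return A list of class `sarsa_run`: `trials` (tibble: `trial`, `steps`,
#'   `true_success`, `true_reward`, `delivered_reward`, `truncated`), `q`
#'   (final `q_table`), `accuracy`, `n_steps`, `seed`, and optionally
#'   `transitions`.
#' @examples
#' \donttest{
#' run <- run_training(n_steps = 20000, accuracy = 1.0, seed = 1)
#' mean(tail(run$trials$true_success, 200))
#' }
#' @export
run_training <- function(n_steps, accuracy = 1.0, params = agent_params(),
                         env = rake_env(), seed, step_cap = 1000,
                         log_transitions = FALSE) {
  if (missing(seed)) stop("`seed` is required")
  if (accuracy < 0.5 || accuracy > 1) stop("accuracy must be in [0.5, 1]")
  set.seed(as.integer(seed))
  res <- sarsa_train_cpp(
    as.integer(n_steps), params$epsilon, params$lambda_trace, params$gamma,
    params$alpha0, params$trace_kind == "replacing", params$q_init, accuracy,
    env$reward_success, env$reward_failure, env$step_penalty,
    env$start_dx, env$start_dy, as.integer(step_cap),
    isTRUE(log_transitions))
  trials <- tibble::tibble(
    trial = seq_along(res$steps), steps = res$steps,
    true_success = res$true_success, true_reward = res$true_reward,
    delivered_reward = res$delivered_reward, truncated = res$truncated)
  q <- q_table()
  q$q <- res$Q
  q$visits <- res$visits
  out <- list(trials = trials, q = q, accuracy = accuracy,
              n_steps = as.integer(n_steps), seed = as.integer(seed),
              params = params)
  if (isTRUE(log_transitions)) {
    out$transitions <- tibble::tibble(
      s = res$tr_s, a = res$tr_a, r = res$tr_r, s2 = res$tr_s2,
      a2 = res$tr_a2, terminal = res$tr_terminal,
      reset_after = res$tr_reset)
  }
  structure(out, class = "sarsa_run")
}

#' @export
print.sarsa_run <- function(x, ...) {
  n <- nrow(x$trials)
  late <- tail(x$trials$true_success, max(1, round(n / 10)))
  cat("<sarsa_run>", x$n_steps, "steps,", n, "trials, reward accuracy",
      x$accuracy, "\n")
  cat(sprintf("late true-success fraction: %.3f\n", mean(late)))
  invisible(x)
}
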