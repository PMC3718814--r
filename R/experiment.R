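#' Noisy reward channel
#'
#' Models the decoder standing between the task and the learner: at each
#' trial end the channel reports the correct outcome class with probability
#' `accuracy` and the opposite class otherwise, mapping classes to the task
#' rewards (+1 success, -0.2 failure by default).
#'
#' @param accuracy Probability of reporting the true class, in `[0.5, 1]`.
#' @param reward_success,reward_failure Reward values delivered for the
#'   reported class.
#' @return A list of class `reward_channel`.
#' @export
reward_channel <- function(accuracy = 1.0, reward_success = 1.0,
                           reward_failure = -0.2) {
  if (!is.finite(accuracy) || accuracy < 0.5 || accuracy > 1) {
    stop("accuracy must lie in [0.5, 1]")
  }
  structure(list(accuracy = accuracy, reward_success = reward_success,
                 reward_failure = reward_failure),
            class = "reward_channel")
}

#' Pass a true outcome through the noisy reward channel
#'
#' With probability `channel$accuracy` the delivered reward is the true
#' outcome's value; otherwise the other class's value. Vectorized over
#' outcomes; consumes one uniform draw per outcome.
#'
#' @param true_outcome Character vector of `"success"` / `"failure"`.
#' @param channel A [reward_channel()].
#' @return Numeric vector of delivered rewards.
#' @export
flip_reward <- function(true_outcome, channel) {
  stopifnot(inherits(channel, "reward_channel"),
            all(true_outcome %in% c("success", "failure")))
  truth <- ifelse(true_outcome == "success",
                  channel$reward_success, channel$reward_failure)
  other <- ifelse(true_outcome == "success",
                  channel$reward_failure, channel$reward_success)
  correct <- runif(length(true_outcome)) < channel$accuracy
  ifelse(correct, truth, other)
}

#' Detect convergence of the trial success record
#'
#' Operationalizes convergence of the value function through the behavior
#' it produces: the convergence trial is the first trial after which the
#' `window`-trial moving success fraction stays within `tol` of its final
#' value for the remainder of training.
#'
#' @param success Logical vector of per-trial true-success indicators, in
#'   trial order (truncated trials count as failures).
#' @param window Moving-window width in trials (default 100).
#' @param tol Tolerance on the moving fraction (default 0.05).
#' @return A list of class `convergence`: `converged` (logical; `FALSE`
#'   when fewer than `window` trials exist), `trial` (index of the
#'   convergence trial), `final_mean` (the last moving fraction).
#' @export
detect_convergence <- function(success, window = 100, tol = 0.05) {
  n <- length(success)
  if (n < window) {
    return(structure(list(converged = FALSE, trial = NA_integer_,
                          final_mean = NA_real_, window = window,
                          tol = tol), class = "convergence"))
  }
  cs <- cumsum(as.numeric(success))
  ma <- (cs[window:n] - c(0, cs)[seq_len(n - window + 1)]) / window
  final_mean <- ma[length(ma)]
  bad <- which(abs(ma - final_mean) > tol)
  trial <- if (length(bad) == 0) window else {
    (max(bad) + 1L) + window - 1L       # endpoint of first settled window
  }
  structure(list(converged = TRUE, trial = as.integer(trial),
                 final_mean = final_mean, window = window, tol = tol),
            class = "convergence")
}

#' Reward-accuracy robustness sweep
#'
#' For every reward-channel accuracy in the grid, trains a fresh
#' SARSA(lambda) agent on the rake task for `n_steps` environment steps
#' (per seed), detects convergence with [detect_convergence()], and
#' reports the true-success fraction over all post-convergence trials.
#' This is the robustness experiment: how much decoder error can the
#' learner absorb while still solving the task?
#'
#' @param accuracies Accuracy grid (default the 10 levels 0.55..1.0).
#' @param n_steps Environment steps per run (default 200000; smaller
#'   values are flagged as `scaled_down` in the result).
#' @param params An [agent_params()].
#' @param env A [rake_env()].
#' @param seeds Integer vector of seeds; one training run per
#'   (accuracy, seed).
#' @param window,tol Convergence criterion (see [detect_convergence()]).
#' @param step_cap Per-episode step cap.
#' @return An object of class `rl_sweep`: list with `runs` (one row per
#'   accuracy x seed: `accuracy`, `seed`, `n_trials`, `convergence_trial`,
#'   `converged`, `success_fraction`, `success_sd`), `summary` (per
#'   accuracy: mean/sd of the fraction over seeds, mean convergence
#'   trial), and the sweep settings.
#' @export
run_accuracy_sweep <- function(accuracies = seq(0.55, 1.0, by = 0.05),
                               n_steps = 200000,
                               params = agent_params(), env = rake_env(),
                               seeds = 1:5, window = 100, tol = 0.05,
                               step_cap = 1000) {
  grid <- tidyr::expand_grid(accuracy = accuracies, seed = seeds)
  runs <- purrr::pmap(grid, function(accuracy, seed) {
    run <- run_training(n_steps = n_steps, accuracy = accuracy,
                        params = params, env = env, seed = seed,
                        step_cap = step_cap)
    succ <- run$trials$true_success
    conv <- detect_convergence(succ, window = window, tol = tol)
    post <- if (conv$converged) succ[conv$trial:length(succ)] else logical()
    tibble::tibble(
      accuracy = accuracy, seed = seed, n_trials = length(succ),
      convergence_trial = conv$trial, converged = conv$converged,
      n_eval_trials = length(post),
      success_fraction = if (length(post)) mean(post) else NA_real_,
      success_sd = if (length(post) > 1) sd(post) else NA_real_)
  })
  runs <- dplyr::bind_rows(runs)
  summary <- runs |>
    dplyr::summarise(
      mean_success = mean(.data$success_fraction),
      sd_success = sd(.data$success_fraction),
      mean_convergence_trial = mean(.data$convergence_trial),
      n_seeds = dplyr::n(),
      .by = "accuracy")
  structure(list(runs = runs, summary = summary,
                 n_steps = as.integer(n_steps),
                 scaled_down = n_steps < 200000,
                 window = window, tol = tol, seeds = seeds,
                 params = params),
            class = "rl_sweep")
}

#' @export
print.rl_sweep <- function(x, ...) {
  cat("<rl_sweep>", x$n_steps, "steps per run,",
      length(x$seeds), "seed(s)",
      if (x$scaled_down) "(scaled down)\n" else "\n")
  print(x$summary)
  invisible(x)
}

#' End-to-end synthetic pipeline: generate, decode, learn
#'
#' Runs the whole chain on synthetic data: generate a session
#' ([generate_session()]), preprocess it ([process_session()]), extract
#' peri-event waveforms, estimate single-trial decoding accuracy with the
#' jackknife SVM ([jackknife_cv()]), then train the SARSA(lambda) agent
#' with a reward channel at that decoded accuracy. The report links the
#' classifier accuracy to the resulting task success fraction.
#'
#' Balanced accuracies below 0.5 (possible by chance on weak contrasts)
#' are clamped to 0.5, the channel's least-informative setting.
#'
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param n_trials Trials in the synthetic session.
#' @param hrf,noise Generator parameters ([hrf_params()],
#'   [noise_params()]).
#' @param tau_s Decoder window end past the outcome (s).
#' @param n_rounds Jackknife rounds.
#' @param rl_steps Training budget for the RL stage.
#' @param params,env Agent and environment configuration.
#' @return A list of class `pipeline_report`: `decoded_accuracy`,
#'   `classifier` (the `classifier_report`), `rl` (per-run tibble row as in
#'   [run_accuracy_sweep()]), `settings`.
#' @export
run_full_pipeline <- function(seed, n_trials = 40, hrf = hrf_params(),
                              noise = noise_params(), tau_s = 15,
                              n_rounds = 100, rl_steps = 200000,
                              params = agent_params(), env = rake_env()) {
  if (missing(seed)) stop("`seed` is required")
  seed <- as.integer(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  session <- stage("simulate",
                   generate_session(n_trials = n_trials, hrf = hrf,
                                    noise = noise, seed = seed))
  hemo <- stage("preprocess", process_session(session))
  peri <- stage("extract", extract_peri_event(hemo))
  feats <- stage("features", build_features(peri, tau_s = tau_s))
  report <- stage("classify",
                  jackknife_cv(feats, n_rounds = n_rounds, seed = seed + 1L))
  acc <- max(0.5, estimate_reward_accuracy(report))
  rl <- stage("rl", run_accuracy_sweep(
    accuracies = acc, n_steps = rl_steps, params = params, env = env,
    seeds = seed + 2L))
  structure(list(
    decoded_accuracy = acc,
    classifier = report,
    rl = rl$runs,
    settings = list(seed = seed, n_trials = n_trials, tau_s = tau_s,
                    n_rounds = n_rounds, rl_steps = rl_steps)
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("decoded accuracy: %.3f (balanced, %d jackknife rounds)\n",
              x$decoded_accuracy, x$classifier$n_rounds))
  cat(sprintf("RL post-convergence success fraction: %.3f (%d eval trials)\n",
              x$rl$success_fraction, x$rl$n_eval_trials))
  invisible(x)
}
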