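#' Tidy a classifier report into a long confusion table
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return A tibble with one row per (actual, predicted) cell: `actual`,
#'   `predicted`, `n`, `pct` (row percentage).
#' @export
tidy.classifier_report <- function(x, ...) {
  cm <- x$confusion
  out <- tidyr::expand_grid(actual = rownames(cm), predicted = colnames(cm))
  out$n <- purrr::map2_int(out$actual, out$predicted,
                           function(a, p) as.integer(cm[a, p]))
  out$pct <- purrr::map2_dbl(out$actual, out$predicted,
                             function(a, p) x$confusion_pct[a, p])
  out
}

#' @rdname tidy.classifier_report
#' @return `glance()`: a one-row tibble with `accuracy` (balanced),
#'   `overall_accuracy`, `n_rounds`, `kernel`, `cost`.
#' @export
glance.classifier_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 overall_accuracy = x$overall_accuracy,
                 n_rounds = x$n_rounds, kernel = x$params$kernel,
                 cost = x$params$cost)
}

#' Tidy an accuracy sweep
#'
#' @param x An `rl_sweep`.
#' @param ... Unused.
#' @return `tidy()`: the per-run tibble (one row per accuracy x seed).
#' @export
tidy.rl_sweep <- function(x, ...) x$runs

#' @rdname tidy.rl_sweep
#' @return `glance()`: a one-row tibble summarizing the sweep settings.
#' @export
glance.rl_sweep <- function(x, ...) {
  tibble::tibble(n_steps = x$n_steps, scaled_down = x$scaled_down,
                 n_accuracies = nrow(x$summary),
                 n_seeds = length(x$seeds),
                 window = x$window, tol = x$tol)
}

#' Tidy a training run
#'
#' @param x A `sarsa_run`.
#' @param ... Unused.
#' @return `tidy()`: the per-trial tibble.
#' @export
tidy.sarsa_run <- function(x, ...) x$trials

#' @rdname tidy.sarsa_run
#' @return `glance()`: one row with trial counts, the convergence trial
#'   under the default criterion, and the post-convergence success
#'   fraction.
#' @export
glance.sarsa_run <- function(x, ...) {
  conv <- detect_convergence(x$trials$true_success)
  post <- if (conv$converged) {
    x$trials$true_success[conv$trial:nrow(x$trials)]
  } else logical()
  tibble::tibble(
    n_trials = nrow(x$trials), n_steps = x$n_steps,
    accuracy = x$accuracy, converged = conv$converged,
    convergence_trial = conv$trial,
    success_fraction = if (length(post)) mean(post) else NA_real_)
}
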