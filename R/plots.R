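#' Plot peri-event group means with significance marks
#'
#' Class means with SEM ribbons per hemoglobin species, with points along
#' the top of each panel marking timesteps where Welch's test is
#' significant.
#'
#' @param object A `nirs_group_stats` from [group_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nirs_group_stats <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(t_rel = object$t_rel, species = object$species,
                   group = object$group1, mean = object$mean1,
                   sem = object$sem1),
    tibble::tibble(t_rel = object$t_rel, species = object$species,
                   group = object$group2, mean = object$mean2,
                   sem = object$sem2))
  sig <- object[object$significant, ]
  ymax <- max(long$mean + long$sem, na.rm = TRUE)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$t_rel, .data$mean,
                                          colour = .data$group,
                                          fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = sprintf("time from %s onset (s)",
                              attr(object, "align") %||% "event"),
                  y = expression(Delta * " concentration (" * mu * "M)"),
                  colour = NULL, fill = NULL)
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(t_rel = sig$t_rel, species = sig$species,
                            mean = ymax * 1.05),
      ggplot2::aes(.data$t_rel, .data$mean),
      inherit.aes = FALSE, shape = 8, size = 1)
  }
  p
}

#' Plot classifier accuracy over feature windows
#'
#' @param object A `window_sweep` from [window_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$tau_s, .data$accuracy,
                                       colour = .data$species_set)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$accuracy - .data$sem,
                                        ymax = .data$accuracy + .data$sem),
                           width = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "window end relative to outcome (s)",
                  y = "balanced accuracy", colour = "features")
}

#' Plot the reward-accuracy robustness sweep
#'
#' Mean post-convergence true-success fraction per reward-channel
#' accuracy, with error bars of one standard deviation across seeds and
#' the identity line (success = accuracy) for reference.
#'
#' @param object An `rl_sweep` from [run_accuracy_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rl_sweep <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$accuracy, .data$mean_success)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_col(width = 0.035, fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_success - .data$sd_success,
      ymax = .data$mean_success + .data$sd_success), width = 0.01) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "reward channel accuracy",
                  y = "post-convergence true-success fraction")
}
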