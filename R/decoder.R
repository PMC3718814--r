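#' Build a single-trial feature matrix from peri-event waveforms
#'
#' One row per trial, concatenating the requested hemoglobin species'
#' waveforms over the window from cue onset to `tau_s` seconds after the
#' outcome. With both species and `tau_s = 0` (cued protocol, 8 s
#' cue-to-outcome at 6 Hz) a row has `2 * (8 * 6 + 1) = 98` features.
#'
#' @param peri A cue-aligned `peri_event_df` (see [extract_peri_event()]).
#' @param species Character subset of `c("hbo", "hbd")`.
#' @param tau_s Window end relative to the outcome, seconds (>= 0).
#' @param outcome_offset_s Cue-to-outcome latency (8 s for the cued task).
#' @return A tibble of class `trial_features`: `trial_id`, `label`, `y`
#'   (+1 reward / -1 penalty), then one column per feature named
#'   `<species>_<index>`, trials in input order.
#' @export
build_features <- function(peri, species = c("hbo", "hbd"), tau_s = 15,
                           outcome_offset_s = 8) {
  if (length(species) == 0) stop("species set must be nonempty")
  species <- match.arg(species, c("hbo", "hbd"), several.ok = TRUE)
  if (tau_s < 0) stop("tau_s must be >= 0")
  fs <- attr(peri, "sample_rate_hz") %||% 6
  t_end <- outcome_offset_s + tau_s
  have <- max(peri$t_rel)
  if (t_end > have + 1e-9) {
    stop("requested window ends at ", t_end, " s but tensor extends to ",
         have, " s")
  }
  sel <- peri$species %in% species & peri$t_rel <= t_end + 1e-9 &
    peri$t_rel >= -1e-9
  df <- peri[sel, c("trial_id", "t_rel", "species", "value", "label")]
  df$feature <- sprintf("%s_%03d", df$species, round(df$t_rel * fs) + 1)
  labels <- dplyr::distinct(df, .data$trial_id, .data$label)
  wide <- tidyr::pivot_wider(df[, c("trial_id", "feature", "value")],
                             names_from = "feature", values_from = "value")
  wide <- wide[match(labels$trial_id, wide$trial_id), ]
  out <- dplyr::bind_cols(
    labels,
    y = ifelse(labels$label == "reward", 1, -1),
    wide[, setdiff(names(wide), "trial_id")]
  )
  class(out) <- c("trial_features", class(out))
  out
}

feature_matrix <- function(features) {
  cols <- setdiff(names(features), c("trial_id", "label", "y"))
  as.matrix(features[, cols])
}

#' Jackknife cross-validated SVM classification of trial desirability
#'
#' For each of `n_rounds` rounds, one trial is selected uniformly at random
#' (with replacement across rounds) and held out, a support-vector machine
#' is trained on the remaining trials, and the held-out trial is
#' classified. Aggregated held-out outcomes form the confusion matrix; the
#' headline accuracy is the balanced accuracy (mean of the per-class
#' correct rates, i.e. the mean of the diagonal of the row-normalized
#' confusion matrix). Rounds whose training split would lose a class
#' entirely are resampled.
#'
#' @param features A `trial_features` tibble from [build_features()].
#' @param n_rounds Number of hold-one-out rounds (default 100).
#' @param kernel SVM kernel, `"linear"` (default) or `"radial"`.
#' @param cost Slack budget C (default 1).
#' @param scale Standardize features before training (default `FALSE`;
#'   per-trial baseline referencing already centers them).
#' @param seed Integer seed for the round sampling.
#' @return An object of class `classifier_report`: list with `confusion`
#'   (actual x predicted counts), `confusion_pct` (row percentages),
#'   `accuracy` (balanced), `overall_accuracy`, `n_rounds`, `rounds`
#'   (per-round tibble), `params`.
#' @export
jackknife_cv <- function(features, n_rounds = 100, kernel = "linear",
                         cost = 1, scale = FALSE, seed) {
  if (missing(seed)) stop("`seed` is required")
  x <- feature_matrix(features)
  yl <- factor(features$label)
  if (nlevels(yl) != 2) stop("need exactly 2 classes, found ", nlevels(yl))
  if (any(table(yl) < 2)) stop("need >= 2 trials per class")
  set.seed(as.integer(seed))
  n <- nrow(x)
  rounds <- vector("list", n_rounds)
  r <- 0L
  while (r < n_rounds) {
    test <- sample.int(n, 1)
    if (sum(yl[-test] == yl[test]) < 1) next   # class vanished: resample
    r <- r + 1L
    fit <- e1071::svm(x[-test, , drop = FALSE], yl[-test], kernel = kernel,
                      cost = cost, scale = scale)
    pred <- predict(fit, x[test, , drop = FALSE])
    rounds[[r]] <- tibble::tibble(
      round = r, trial_id = features$trial_id[test],
      actual = as.character(yl[test]), predicted = as.character(pred))
  }
  rounds <- dplyr::bind_rows(rounds)
  rounds$correct <- rounds$actual == rounds$predicted
  lev <- levels(yl)
  confusion <- table(factor(rounds$actual, lev), factor(rounds$predicted, lev))
  names(dimnames(confusion)) <- c("actual", "predicted")
  pct <- prop.table(confusion, 1) * 100
  structure(list(
    confusion = unclass(confusion), confusion_pct = unclass(pct),
    accuracy = mean(diag(prop.table(confusion, 1))),
    overall_accuracy = mean(rounds$correct),
    n_rounds = n_rounds, rounds = rounds,
    params = list(kernel = kernel, cost = cost, scale = scale,
                  seed = as.integer(seed))
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report>", x$n_rounds, "jackknife rounds,",
      x$params$kernel, "kernel\n")
  cat(sprintf("balanced accuracy %.1f%% (overall %.1f%%)\n",
              100 * x$accuracy, 100 * x$overall_accuracy))
  print(round(x$confusion_pct, 1))
  invisible(x)
}

#' Classifier accuracy over feature windows and species sets
#'
#' Repeats [jackknife_cv()] for every combination of window end `tau_s`
#' (seconds past the outcome; all windows start at cue onset) and
#' hemoglobin species set, reporting balanced accuracy with its standard
#' error (SEM of the per-round correctness indicator).
#'
#' @param peri A cue-aligned `peri_event_df`.
#' @param tau_s_list Numeric vector of window ends relative to outcome.
#' @param species_sets List of species subsets, e.g.
#'   `list("hbo", "hbd", c("hbo", "hbd"))`.
#' @param n_rounds Jackknife rounds per cell.
#' @param seed Integer seed.
#' @param ... Passed to [jackknife_cv()] (e.g. `kernel`, `cost`).
#' @return A tibble of class `window_sweep`: `tau_s`, `species_set`,
#'   `accuracy`, `sem`, `n_rounds`.
#' @export
window_sweep <- function(peri, tau_s_list = seq(0, 15, by = 3),
                         species_sets = list("hbo", "hbd", c("hbo", "hbd")),
                         n_rounds = 100, seed, ...) {
  if (missing(seed)) stop("`seed` is required")
  grid <- tidyr::expand_grid(tau_s = tau_s_list,
                             set_id = seq_along(species_sets))
  res <- purrr::pmap(grid, function(tau_s, set_id) {
    sp <- species_sets[[set_id]]
    feats <- build_features(peri, species = sp, tau_s = tau_s)
    rep <- jackknife_cv(feats, n_rounds = n_rounds,
                        seed = seed + 131L * set_id + round(97 * tau_s), ...)
    tibble::tibble(
      tau_s = tau_s, species_set = paste(sp, collapse = "+"),
      accuracy = rep$accuracy,
      sem = sd(rep$rounds$correct) / sqrt(nrow(rep$rounds)),
      n_rounds = n_rounds)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("window_sweep", class(out))
  out
}

#' Balanced accuracy of a classifier report, for the reward channel
#'
#' Reduces a [jackknife_cv()] report (or a raw actual x predicted confusion
#' matrix) to the balanced accuracy: the mean of the per-class correct
#' rates. This is the probability estimate fed to the reinforcement
#' learner's noisy reward channel.
#'
#' @param report A `classifier_report` or a 2x2 confusion count matrix.
#' @return Accuracy in `[0, 1]`.
#' @export
estimate_reward_accuracy <- function(report) {
  cm <- if (inherits(report, "classifier_report")) report$confusion else
    as.matrix(report)
  if (any(dim(cm) != 2) || sum(cm) == 0) {
    stop("report must contain a nonempty 2x2 confusion matrix")
  }
  mean(diag(prop.table(cm, 1)))
}
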