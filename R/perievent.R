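#' Extract labelled peri-event windows from a hemoglobin series
#'
#' Cuts the channel-averaged hemoglobin series into per-trial windows
#' aligned to the cue or the outcome, attaching each trial's outcome label
#' and artifact tag. The default window runs from cue onset to 15 s after
#' the outcome. Trials whose requested window is not fully covered by the
#' series are dropped and counted in the `dropped` attribute.
#'
#' @param hemo A `hemo_series` from [process_session()].
#' @param events Trial events; defaults to the events attached to `hemo`.
#' @param align Alignment event: `"cue"` or `"outcome"`.
#' @param window Length-2 numeric, window start/end in seconds relative to
#'   the alignment event. Default: cue-aligned, ending 15 s post outcome.
#' @return A long tibble of class `peri_event_df` with columns `trial_id`,
#'   `t_rel` (seconds relative to the alignment event), `species`
#'   (`hbo`/`hbd`/`hbtot`), `value` (uM), `label`, `tag`. Attributes:
#'   `align`, `window`, `sample_rate_hz`, `dropped`.
#' @export
extract_peri_event <- function(hemo, events = attr(hemo, "events"),
                               align = c("cue", "outcome"), window = NULL) {
  align <- match.arg(align)
  stopifnot(is.data.frame(hemo),
            all(c("trial_id", "t_rel", "d_hbo", "d_hbd") %in% names(hemo)))
  fs <- attr(hemo, "sample_rate_hz") %||% 6
  if (nrow(events) == 0) {
    out <- tibble::tibble(trial_id = integer(), t_rel = numeric(),
                          species = character(), value = numeric(),
                          label = character(), tag = logical())
    attr(out, "align") <- align
    attr(out, "window") <- window
    attr(out, "sample_rate_hz") <- fs
    attr(out, "dropped") <- 0L
    class(out) <- c("peri_event_df", class(out))
    return(out)
  }
  if (is.null(window)) {
    off <- if (align == "cue") {
      stats::median(events$outcome_onset_s - events$cue_onset_s)
    } else 0
    window <- c(0, off + 15)
  }
  idx0 <- round(window[1] * fs)
  idx1 <- round(window[2] * fs)
  grid <- idx0:idx1

  pieces <- vector("list", nrow(events))
  dropped <- 0L
  for (i in seq_len(nrow(events))) {
    shift <- if (align == "outcome") {
      round((events$outcome_onset_s[i] - events$cue_onset_s[i]) * fs)
    } else 0L
    tr <- hemo[hemo$trial_id == events$trial_id[i], ]
    ti <- round(tr$t_rel * fs) - shift
    sel <- match(grid, ti)
    if (nrow(tr) == 0 || anyNA(sel)) {
      dropped <- dropped + 1L
      next
    }
    pieces[[i]] <- tibble::tibble(
      trial_id = events$trial_id[i],
      t_rel = grid / fs,
      hbo = tr$d_hbo[sel], hbd = tr$d_hbd[sel], hbtot = tr$d_hbtot[sel],
      label = events$outcome_class[i], tag = events$artifact_tag[i]
    )
  }
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    out <- tibble::tibble(trial_id = integer(), t_rel = numeric(),
                          hbo = numeric(), hbd = numeric(),
                          hbtot = numeric(), label = character(),
                          tag = logical())
  }
  out <- tidyr::pivot_longer(out, c("hbo", "hbd", "hbtot"),
                             names_to = "species", values_to = "value")
  out <- out[, c("trial_id", "t_rel", "species", "value", "label", "tag")]
  attr(out, "align") <- align
  attr(out, "window") <- window
  attr(out, "sample_rate_hz") <- fs
  attr(out, "dropped") <- dropped
  class(out) <- c("peri_event_df", class(out))
  out
}

#' Per-timestep group statistics with Welch's t-test
#'
#' For every peri-event timestep and hemoglobin species, computes the group
#' means and standard errors and tests the two groups against each other
#' with Welch's unequal-variance two-sample t-test
#' (Welch-Satterthwaite degrees of freedom), flagging timesteps significant
#' at `alpha`. Grouping is by outcome label (default) or by artifact tag,
#' so the same routine reproduces both reward-vs-penalty and
#' movement-vs-quiet comparisons. P-values are reported per timestep
#' without multiple-testing correction by default; `correction =
#' "bonferroni"` adjusts across timesteps within each species.
#'
#' @param peri A `peri_event_df` from [extract_peri_event()].
#' @param group_by `"label"` or `"tag"`.
#' @param alpha Significance level for the per-timestep flag.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return A tibble of class `nirs_group_stats`: `t_rel`, `species`,
#'   `group1`, `group2`, `n1`, `n2`, `mean1`, `sem1`, `mean2`, `sem2`,
#'   `t`, `p`, `significant`.
#' @export
group_stats <- function(peri, group_by = c("label", "tag"), alpha = 0.05,
                        correction = c("none", "bonferroni")) {
  group_by <- match.arg(group_by)
  correction <- match.arg(correction)
  g <- as.character(peri[[group_by]])
  lev <- sort(unique(g))
  if ("reward" %in% lev) lev <- c("reward", setdiff(lev, "reward"))
  if (length(lev) != 2) {
    stop("grouping variable must have exactly 2 levels, found ",
         length(lev))
  }
  per_trial <- dplyr::distinct(
    dplyr::mutate(peri, .g = g), .data$trial_id, .data$.g)
  if (any(table(per_trial$.g) < 2)) {
    stop("each group needs at least 2 trials")
  }
  df <- dplyr::mutate(peri, .g = g)
  out <- df |>
    dplyr::summarise(
      n1 = sum(.data$.g == lev[1]), n2 = sum(.data$.g == lev[2]),
      mean1 = mean(.data$value[.data$.g == lev[1]]),
      mean2 = mean(.data$value[.data$.g == lev[2]]),
      sem1 = sd(.data$value[.data$.g == lev[1]]) / sqrt(.data$n1),
      sem2 = sd(.data$value[.data$.g == lev[2]]) / sqrt(.data$n2),
      .welch = list(
        tryCatch(t.test(.data$value[.data$.g == lev[1]],
                        .data$value[.data$.g == lev[2]],
                        var.equal = FALSE),
                 error = function(e) NULL)),
      .by = c("t_rel", "species"))
  out$t <- vapply(out$.welch, function(w)
    if (is.null(w)) 0 else unname(w$statistic), numeric(1))
  out$p <- vapply(out$.welch, function(w)
    if (is.null(w)) 1 else w$p.value, numeric(1))
  out$.welch <- NULL
  if (correction == "bonferroni") {
    out <- out |>
      dplyr::mutate(p = stats::p.adjust(.data$p, "bonferroni"),
                    .by = "species")
  }
  out$group1 <- lev[1]
  out$group2 <- lev[2]
  out$significant <- out$p < alpha
  out <- out[, c("t_rel", "species", "group1", "group2", "n1", "n2",
                 "mean1", "sem1", "mean2", "sem2", "t", "p", "significant")]
  attr(out, "alpha") <- alpha
  attr(out, "align") <- attr(peri, "align")
  class(out) <- c("nirs_group_stats", class(out))
  out
}
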