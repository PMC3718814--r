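#' Zero-phase band-pass filter for NIRS channel data
#'
#' Butterworth band-pass (default 0.01-1 Hz, the band retaining slow
#' hemodynamics while rejecting drift below and cardiac/instrument noise
#' above) applied forward and backward with [signal::filtfilt()], so the
#' output is zero-phase and the effective magnitude response is squared.
#' The default `order = 2` per band edge realizes a 4th-order band-pass.
#'
#' @param x Numeric vector (one channel, one wavelength, optical density).
#' @param low_hz,high_hz Band edges in Hz; `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Butterworth prototype order per band edge.
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, low_hz = 0.01, high_hz = 1.0, fs = 6, order = 2) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("need 0 < low_hz < high_hz < fs/2")
  }
  # filtfilt needs > 3x the filter length to settle its edge extensions
  min_len <- 3 * (2 * 2 * order + 1)
  if (length(x) <= min_len) {
    stop("series too short to filter: length ", length(x),
         " <= ", min_len)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  sum(p[half][f[half] > f_lo & f[half] <= f_hi])
}

#' Reject channels with inadequate signal-to-noise ratio
#'
#' SNR is the ratio of spectral power inside the hemodynamic band
#' (0.01-1 Hz) to power above 1 Hz, computed from the raw (unfiltered)
#' optical density per wavelength. A channel is rejected when its SNR at
#' *either* wavelength falls below `threshold`; channels carrying mostly
#' broadband noise (e.g. bad optode coupling) fail this test, since white
#' noise splits its power roughly 1:2 across the two bands at a 6 Hz frame
#' rate.
#'
#' @param session A `nirs_session`.
#' @param threshold Minimum acceptable SNR (dimensionless, default 2).
#' @return A tibble with one row per channel: `channel`, `snr_760`,
#'   `snr_850`, `keep`.
#' @export
snr_reject <- function(session, threshold = 2.0) {
  stopifnot(inherits(session, "nirs_session"))
  fs <- session$meta$sample_rate_hz
  chans <- session$channels$channel
  if (length(chans) < 1) stop("session has no channels")
  snr1 <- function(col) {
    x <- session$od[[col]]
    sig <- band_power(x, fs, 0.01, 1)
    noi <- band_power(x, fs, 1, fs / 2)
    if (noi == 0) Inf else sig / noi
  }
  out <- tibble::tibble(
    channel = chans,
    snr_760 = vapply(paste0(chans, "_760"), snr1, numeric(1)),
    snr_850 = vapply(paste0(chans, "_850"), snr1, numeric(1))
  )
  out$keep <- pmin(out$snr_760, out$snr_850) >= threshold
  if (!any(out$keep)) {
    stop("all channels rejected at SNR threshold ", threshold,
         "; review the threshold or the recording")
  }
  out
}

#' Reference a window of optical density to its pre-cue baseline
#'
#' Subtracts, per data column, the mean over the baseline window
#' (`baseline_s` seconds immediately before `cue_onset_s`) from every
#' sample, yielding baseline-referenced absorbance changes.
#'
#' @param od Data frame with a `time_s` column and numeric data columns.
#' @param cue_onset_s Cue onset time (s).
#' @param baseline_s Baseline duration before the cue (s).
#' @return A tibble shaped like `od` with baselined data columns.
#' @export
baseline_reference <- function(od, cue_onset_s, baseline_s = 10) {
  stopifnot(is.data.frame(od), "time_s" %in% names(od))
  in_base <- od$time_s >= cue_onset_s - baseline_s & od$time_s < cue_onset_s
  if (!any(in_base)) {
    stop("baseline window [", cue_onset_s - baseline_s, ", ", cue_onset_s,
         ") contains no samples")
  }
  out <- tibble::as_tibble(od)
  for (col in setdiff(names(out), "time_s")) {
    out[[col]] <- out[[col]] - mean(out[[col]][in_base])
  }
  out
}

#' Average per-channel hemoglobin series across accepted channels
#'
#' Unweighted mean of `d_hbo` and `d_hbd` across the accepted channels at
#' each grouping key (all columns other than `channel`, `d_hbo`, `d_hbd`),
#' with `d_hbtot` computed as their sum.
#'
#' @param df Long tibble with columns `channel`, `d_hbo`, `d_hbd` plus any
#'   grouping columns (e.g. `trial_id`, `time_s`).
#' @param channel_mask Character vector of accepted channel names, or a
#'   tibble from [snr_reject()] (its `keep` column is used).
#' @return A tibble keyed by the grouping columns with `d_hbo`, `d_hbd`,
#'   `d_hbtot`.
#' @export
average_channels <- function(df, channel_mask = unique(df$channel)) {
  if (is.data.frame(channel_mask)) {
    channel_mask <- channel_mask$channel[channel_mask$keep]
  }
  if (length(channel_mask) == 0) stop("channel mask is empty")
  keys <- setdiff(names(df), c("channel", "d_hbo", "d_hbd"))
  df |>
    dplyr::filter(.data$channel %in% channel_mask) |>
    dplyr::summarise(d_hbo = mean(.data$d_hbo), d_hbd = mean(.data$d_hbd),
                     .by = dplyr::all_of(keys)) |>
    dplyr::mutate(d_hbtot = .data$d_hbo + .data$d_hbd)
}

#' Full preprocessing: raw session to channel-averaged hemoglobin series
#'
#' Applies the preprocessing chain to every trial of a session: band-pass
#' filter each channel/wavelength ([bandpass()]), reject low-SNR channels
#' ([snr_reject()] on the unfiltered data), then per trial reference the
#' filtered optical density to the 10 s pre-cue baseline
#' ([baseline_reference()]), invert the modified Beer-Lambert law per
#' channel ([mbll_invert()]), and average across accepted channels
#' ([average_channels()]). Series are produced only over trial windows
#' (baseline start through 15 s post-outcome). Trials whose window falls
#' partly outside the recording are dropped (with a warning reporting the
#' count).
#'
#' @param session A `nirs_session`.
#' @param low_hz,high_hz Filter band (Hz).
#' @param filter Apply the band-pass (default `TRUE`); `FALSE` skips
#'   filtering, leaving the chain exactly linear (useful for validating
#'   the forward/inverse identity on noise-free data).
#' @param snr_threshold SNR rejection threshold; `0` keeps all channels.
#' @param baseline_s Pre-cue baseline duration (s).
#' @param post_outcome_s Post-outcome extent of the trial window (s).
#' @return A tibble of class `hemo_series`: `trial_id`, `time_s`, `t_rel`
#'   (seconds relative to cue onset), `d_hbo`, `d_hbd`, `d_hbtot` (uM), with
#'   attributes `channel_mask` (the [snr_reject()] table) and `events`.
#' @examples
#' s <- generate_session(n_trials = 4, seed = 1)
#' h <- process_session(s)
#' head(h)
#' @export
process_session <- function(session, low_hz = 0.01, high_hz = 1.0,
                            filter = TRUE, snr_threshold = 2.0,
                            baseline_s = 10, post_outcome_s = 15) {
  stopifnot(inherits(session, "nirs_session"))
  fs <- session$meta$sample_rate_hz
  em <- session$meta$extinction
  mask <- if (snr_threshold > 0) snr_reject(session, snr_threshold) else {
    tibble::tibble(channel = session$channels$channel,
                   snr_760 = NA_real_, snr_850 = NA_real_, keep = TRUE)
  }
  keep <- mask$channel[mask$keep]

  filt <- session$od
  if (filter) {
    for (col in setdiff(names(filt), "time_s")) {
      filt[[col]] <- bandpass(filt[[col]], low_hz, high_hz, fs = fs)
    }
  }

  time_s <- filt$time_s
  ev <- session$events
  dropped <- 0L
  pieces <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    t0 <- ev$cue_onset_s[i] - baseline_s
    t1 <- ev$outcome_onset_s[i] + post_outcome_s
    if (t0 < min(time_s) - 1e-9 || t1 > max(time_s) + 1e-9) {
      dropped <- dropped + 1L
      next
    }
    win <- which(time_s >= t0 - 1e-9 & time_s <= t1 + 1e-9)
    base <- which(time_s >= t0 - 1e-9 & time_s < ev$cue_onset_s[i] - 1e-9)
    hbo <- hbd <- matrix(0, nrow = length(win), ncol = length(keep))
    for (k in seq_along(keep)) {
      a760 <- filt[[paste0(keep[k], "_760")]]
      a850 <- filt[[paste0(keep[k], "_850")]]
      dc <- mbll_invert(data.frame(
        da_760 = a760[win] - mean(a760[base]),
        da_850 = a850[win] - mean(a850[base])), em)
      hbo[, k] <- dc$d_hbo
      hbd[, k] <- dc$d_hbd
    }
    tw <- time_s[win]
    pieces[[i]] <- tibble::tibble(
      trial_id = ev$trial_id[i],
      time_s = tw,
      t_rel = round((tw - ev$cue_onset_s[i]) * fs) / fs,
      d_hbo = rowMeans(hbo), d_hbd = rowMeans(hbd)
    )
  }
  if (dropped > 0) {
    warning(dropped, " trial(s) dropped: window outside the recording")
  }
  out <- dplyr::bind_rows(pieces)
  out$d_hbtot <- out$d_hbo + out$d_hbd
  attr(out, "channel_mask") <- mask
  attr(out, "events") <- ev[ev$trial_id %in% unique(out$trial_id), ]
  attr(out, "sample_rate_hz") <- fs
  class(out) <- c("hemo_series", class(out))
  out
}
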