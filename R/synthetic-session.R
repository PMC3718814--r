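#' Hemodynamic response parameters for the synthetic generator
#'
#' Describes the class-conditional hemodynamic response embedded in synthetic
#' sessions: for each outcome class (`reward`, `penalty`) and hemoglobin
#' species (`hbo`, `hbd`) a biphasic outcome-locked kernel (early dip followed
#' by a slower peak, returning to baseline over `return_tau_s` seconds) plus a
#' linear anticipatory ramp between cue and outcome. Amplitudes are in uM.
#'
#' The defaults encode the qualitative desirability contrast the decoder
#' relies on: oxyhemoglobin rises after desirable outcomes but not after
#' undesirable ones (which instead show a deeper initial dip), while
#' deoxyhemoglobin responds similarly in the first seconds for both classes
#' but returns to baseline more slowly after undesirable outcomes.
#'
#' @param params Optional data frame overriding the defaults; must contain
#'   columns `outcome_class`, `species`, `dip_amplitude`, `dip_latency_s`,
#'   `peak_amplitude`, `peak_latency_s`, `return_tau_s`,
#'   `anticipatory_amplitude`.
#'
#' @return A tibble of class `hrf_params`, one row per (class, species).
#' @export
hrf_params <- function(params = NULL) {
  if (is.null(params)) {
    params <- tibble::tribble(
      ~outcome_class, ~species, ~dip_amplitude, ~dip_latency_s,
      ~peak_amplitude, ~peak_latency_s, ~return_tau_s, ~anticipatory_amplitude,
      "reward",  "hbo", 0.25, 1.5, 0.70, 6, 5.0,  0.20,
      "penalty", "hbo", 0.50, 2.0, 0.10, 6, 6.0, -0.10,
      "reward",  "hbd", 0.50, 4.0, 0.00, 8, 3.5, -0.15,
      "penalty", "hbd", 0.50, 4.0, 0.00, 8, 10.0, -0.05
    )
  }
  params <- tibble::as_tibble(params)
  need <- c("outcome_class", "species", "dip_amplitude", "dip_latency_s",
            "peak_amplitude", "peak_latency_s", "return_tau_s",
            "anticipatory_amplitude")
  if (!all(need %in% names(params))) {
    stop("hrf_params needs columns: ", paste(need, collapse = ", "))
  }
  num <- params[setdiff(need, c("outcome_class", "species"))]
  if (!all(vapply(num, function(x) all(is.finite(x)), logical(1)))) {
    stop("all hrf parameters must be finite")
  }
  if (any(params$return_tau_s <= 0) ||
      any(params$dip_latency_s <= 0) || any(params$peak_latency_s <= 0)) {
    stop("latencies and time constants must be positive")
  }
  pk <- function(cl) params$peak_amplitude[params$outcome_class == cl &
                                             params$species == "hbo"]
  if (length(pk("reward")) == 1 && length(pk("penalty")) == 1 &&
      pk("reward") <= pk("penalty") &&
      !(pk("reward") == 0 && pk("penalty") == 0)) {   # allow the null config
    stop("reward-class HbO peak amplitude must exceed the penalty-class ",
         "peak: without that contrast desirability is not separable")
  }
  class(params) <- c("hrf_params", class(params))
  params
}

#' Physiological and instrumental noise parameters
#'
#' Amplitudes are in uM-equivalent units: they are scaled into optical
#' density through the mean extinction coefficient so that, e.g., a 0.3
#' uM-equivalent white noise floor is commensurate with a 1 uM hemodynamic
#' response. Oscillatory components model cardiac pulsation, respiration and
#' Meyer (slow blood-pressure) waves; `drift_coeff` sets the per-sample
#' standard deviation of a random-walk baseline drift. `dead_channel_ids`
#' lists channels that carry no signal (white noise only), emulating bad
#' optode coupling; `artifact_amp` is the amplitude of the broadband burst
#' added to movement-tagged trials (same sign at both wavelengths).
#'
#' @param white_sd White noise SD (uM-equivalent).
#' @param drift_coeff Random-walk drift increment SD per sample.
#' @param cardiac_hz,cardiac_amp Cardiac frequency (Hz) and amplitude.
#' @param resp_hz,resp_amp Respiratory frequency and amplitude.
#' @param meyer_hz,meyer_amp Meyer-wave frequency and amplitude.
#' @param gain_jitter_sd SD of the multiplicative per-channel gain jitter.
#' @param trial_amp_sd SD of the multiplicative per-trial response
#'   amplitude jitter (hemodynamic responses vary substantially from trial
#'   to trial; this is what keeps single-trial decoding below ceiling).
#' @param dead_channel_ids Integer indices of dead channels.
#' @param artifact_amp Amplitude of the movement-artifact burst.
#'
#' @details White noise is independent per channel and wavelength
#'   (detector shot noise); the drift and the three oscillatory components
#'   are systemic, shared by all live channels, so they do not average out
#'   across channels the way instrument noise does.
#'
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(white_sd = 0.2, drift_coeff = 0.04,
                         cardiac_hz = 2.0, cardiac_amp = 0.15,
                         resp_hz = 0.6, resp_amp = 0.4,
                         meyer_hz = 0.1, meyer_amp = 0.6,
                         gain_jitter_sd = 0.1, trial_amp_sd = 0.35,
                         dead_channel_ids = integer(),
                         artifact_amp = 2.0) {
  amps <- c(white_sd, drift_coeff, cardiac_amp, resp_amp, meyer_amp,
            gain_jitter_sd, trial_amp_sd, artifact_amp)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    stop("noise amplitudes must be finite and non-negative")
  }
  freqs <- c(cardiac_hz, resp_hz, meyer_hz)
  if (any(freqs <= 0) || any(freqs >= 3)) {
    stop("oscillation frequencies must lie in (0, 3) Hz (below Nyquist ",
         "at the 6 Hz frame rate)")
  }
  structure(list(white_sd = white_sd, drift_coeff = drift_coeff,
                 cardiac_hz = cardiac_hz, cardiac_amp = cardiac_amp,
                 resp_hz = resp_hz, resp_amp = resp_amp,
                 meyer_hz = meyer_hz, meyer_amp = meyer_amp,
                 gain_jitter_sd = gain_jitter_sd,
                 trial_amp_sd = trial_amp_sd,
                 dead_channel_ids = as.integer(dead_channel_ids),
                 artifact_amp = artifact_amp),
            class = "noise_params")
}

# Unit-peak gamma-shaped bump with mode `lat` and width scale `s`.
gamma_bump <- function(t, lat, s) {
  k <- pmax((lat / s)^2, 1.05)          # shape from latency/width ratio
  out <- numeric(length(t))
  pos <- t > 0
  x <- t[pos] / lat
  out[pos] <- x^k * exp(k * (1 - x))
  out
}

# Outcome-locked biphasic kernel, t in seconds since outcome onset.
# return_tau_s sets the recovery timescale of the terminal phase: the peak
# when one is present, otherwise the dip itself (monophasic responses like
# the deoxyhemoglobin dip recover over return_tau_s).
hrf_kernel <- function(t, dip_amplitude, dip_latency_s, peak_amplitude,
                       peak_latency_s, return_tau_s) {
  dip_width <- if (peak_amplitude == 0) return_tau_s else dip_latency_s
  peak_amplitude * gamma_bump(t, peak_latency_s, return_tau_s) -
    dip_amplitude * gamma_bump(t, dip_latency_s, dip_width)
}

# Anticipatory ramp: 0 at cue, `amp` at outcome, linear decay over 3 s after.
anticipatory_wave <- function(t_since_cue, cue_to_outcome_s, amp) {
  up <- pmin(pmax(t_since_cue / cue_to_outcome_s, 0), 1)
  down <- pmin(pmax((t_since_cue - cue_to_outcome_s) / 3, 0), 1)
  amp * (up - down * up)
}

#' Generate a synthetic dual-wavelength NIRS session
#'
#' Simulates a complete recording session: a schedule of reward/penalty
#' trials (cued protocol: 10 s baseline, 8 s cue-to-outcome cursor travel,
#' 15 s post-outcome window, exponential inter-trial interval; uncued
#' protocol: pseudo-Poisson outcome deliveries with a minimum spacing),
#' class-conditional hemodynamic concentration waveforms per
#' [hrf_params()], forward conversion to 760/850 nm optical density via the
#' modified Beer-Lambert law, and additive physiological/instrumental noise
#' per [noise_params()]. Ground-truth waveforms and labels are retained for
#' validation.
#'
#' @param n_trials Number of trials (>= 1).
#' @param reward_fraction Probability that a trial is a reward trial.
#' @param hrf An [hrf_params()] table.
#' @param noise A [noise_params()] list.
#' @param cued Logical; cued protocol (default) or uncued deliveries.
#' @param color_scheme `"standard"` (blue cue predicts reward) or
#'   `"reversed"`.
#' @param n_channels Number of source-detector channels.
#' @param em An [extinction_matrix()].
#' @param sample_rate_hz Frame rate; fixed at 6 Hz.
#' @param iti_mean_s,iti_min_s Cued-protocol inter-trial interval:
#'   exponential mean and truncation minimum (seconds), applied between the
#'   end of one post-outcome window and the next cue.
#' @param uncued_mean_s,uncued_min_s Uncued-protocol inter-event interval:
#'   exponential (Poisson process) mean and hard minimum.
#' @param artifact_rate Fraction of trials tagged with a movement artifact.
#' @param seed Integer seed; required, so sessions are reproducible.
#'
#' @return An object of class `nirs_session`: a list with
#'   * `od`: tibble of optical density, `time_s` plus one column per
#'     channel x wavelength named like `S1_D1_760`;
#'   * `events`: tibble of trial events (`trial_id`, `cue_onset_s`,
#'     `outcome_onset_s`, `outcome_class`, `cue_color`, `cued`,
#'     `artifact_tag`);
#'   * `channels`: tibble (`channel`, `source`, `detector`);
#'   * `meta`: list of generator settings;
#'   * `ground_truth`: embedded class-mean concentration waveforms and
#'     per-channel gains (for validation only).
#' @examples
#' s <- generate_session(n_trials = 4, seed = 1)
#' s$events
#' @export
generate_session <- function(n_trials = 40, reward_fraction = 0.5,
                             hrf = hrf_params(), noise = noise_params(),
                             cued = TRUE, color_scheme = c("standard", "reversed"),
                             n_channels = 8, em = extinction_matrix(),
                             sample_rate_hz = 6,
                             iti_mean_s = 20, iti_min_s = 5,
                             uncued_mean_s = 60, uncued_min_s = 40,
                             artifact_rate = 0.05, seed) {
  if (missing(seed)) stop("`seed` is required for reproducible sessions")
  color_scheme <- match.arg(color_scheme)
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (reward_fraction < 0 || reward_fraction > 1) {
    stop("reward_fraction must lie in [0, 1]")
  }
  hrf <- hrf_params(hrf)
  if (!inherits(noise, "noise_params")) stop("`noise` must be noise_params()")
  em <- check_extinction(em)
  fs <- sample_rate_hz
  if (fs != 6) stop("sample_rate_hz is fixed at 6 Hz")

  set.seed(as.integer(seed))

  snap <- function(t) round(t * fs) / fs
  if (cued) {
    gaps <- pmax(iti_min_s, rexp(n_trials, rate = 1 / iti_mean_s))
    cue <- numeric(n_trials)
    cue[1] <- 10
    if (n_trials > 1) {
      for (i in 2:n_trials) cue[i] <- cue[i - 1] + 8 + 15 + gaps[i - 1]
    }
    cue <- snap(cue)
    outcome <- cue + 8
  } else {
    gaps <- pmax(uncued_min_s, rexp(n_trials, rate = 1 / uncued_mean_s))
    gaps <- ceiling(gaps * fs) / fs        # snap up so the minimum gap holds
    outcome <- 15 + cumsum(c(0, gaps[-n_trials]))
    cue <- outcome
  }
  t_end <- outcome[n_trials] + 15 + 5
  n <- floor(t_end * fs) + 1
  time_s <- (seq_len(n) - 1) / fs

  is_reward <- runif(n_trials) < reward_fraction
  outcome_class <- ifelse(is_reward, "reward", "penalty")
  cue_color <- if (color_scheme == "standard") {
    ifelse(is_reward, "blue", "red")
  } else {
    ifelse(is_reward, "red", "blue")
  }
  artifact_tag <- runif(n_trials) < artifact_rate
  events <- tibble::tibble(
    trial_id = seq_len(n_trials), cue_onset_s = cue,
    outcome_onset_s = outcome, outcome_class = outcome_class,
    cue_color = cue_color, cued = cued, artifact_tag = artifact_tag
  )

  # Clean chromophore concentration series shared by all live channels,
  # with a multiplicative per-trial response amplitude jitter.
  trial_amp <- pmax(0, 1 + rnorm(n_trials, 0, noise$trial_amp_sd))
  conc <- matrix(0, nrow = n, ncol = 2, dimnames = list(NULL, c("hbd", "hbo")))
  for (sp in c("hbd", "hbo")) {
    for (i in seq_len(n_trials)) {
      p <- hrf[hrf$species == sp & hrf$outcome_class == outcome_class[i], ]
      tc <- time_s - outcome[i]
      w <- hrf_kernel(tc, p$dip_amplitude, p$dip_latency_s,
                      p$peak_amplitude, p$peak_latency_s, p$return_tau_s)
      if (cued) {
        w <- w + anticipatory_wave(time_s - cue[i], 8, p$anticipatory_amplitude)
      }
      conc[, sp] <- conc[, sp] + trial_amp[i] * w
    }
  }

  clean_dA <- forward_mbll(
    data.frame(d_hbd = conc[, "hbd"], d_hbo = conc[, "hbo"]), em)
  od_per_um <- mean(em$E) * 1e-6 * em$path_length_cm  # uM-equivalent scale

  gains <- 1 + rnorm(n_channels, 0, noise$gain_jitter_sd)
  artifact_series <- numeric(n)
  tagged <- which(artifact_tag)
  for (i in tagged) {
    idx <- which(time_s >= outcome[i] - 1 & time_s <= outcome[i] + 2)
    artifact_series[idx] <- artifact_series[idx] +
      noise$artifact_amp * exp(-((time_s[idx] - outcome[i] - 0.5) / 0.8)^2)
  }

  # Systemic physiology (drift + oscillations) is shared across channels;
  # white detector noise is drawn independently per channel/wavelength.
  shared_physio <- function() {
    x <- numeric(n)
    if (noise$drift_coeff > 0) x <- x + cumsum(rnorm(n, 0, noise$drift_coeff))
    for (comp in list(c(noise$cardiac_hz, noise$cardiac_amp),
                      c(noise$resp_hz, noise$resp_amp),
                      c(noise$meyer_hz, noise$meyer_amp))) {
      if (comp[2] > 0) {
        x <- x + comp[2] * sin(2 * pi * comp[1] * time_s + runif(1, 0, 2 * pi))
      }
    }
    x
  }
  physio <- list(`760` = shared_physio(), `850` = shared_physio())

  n_src <- max(1L, ceiling(n_channels / 4))
  channels <- tibble::tibble(
    source = rep(seq_len(n_src), each = 4, length.out = n_channels),
    detector = rep(1:4, times = n_src, length.out = n_channels)
  )
  channels$channel <- paste0("S", channels$source, "_D", channels$detector)

  any_noise <- noise$white_sd + noise$drift_coeff + noise$cardiac_amp +
    noise$resp_amp + noise$meyer_amp > 0
  od <- tibble::tibble(time_s = time_s)
  for (ch in seq_len(n_channels)) {
    dead <- ch %in% noise$dead_channel_ids
    burst <- artifact_series * od_per_um
    for (wl in c("760", "850")) {
      sig <- if (dead) numeric(n) else {
        gains[ch] * clean_dA[[paste0("da_", wl)]] + physio[[wl]] * od_per_um
      }
      ns <- if (any_noise) {
        rnorm(n, 0, if (dead) max(noise$white_sd, 0.3) else noise$white_sd) *
          od_per_um
      } else numeric(n)
      od[[paste0(channels$channel[ch], "_", wl)]] <-
        sig + ns + if (dead) 0 else burst
    }
  }

  # Ground-truth class-mean waveforms on the cue -> outcome + 15 s grid
  # (computed as integer multiples of 1/fs so it matches extraction exactly).
  t_rel <- (0:(23 * 6)) / 6
  truth <- tidyr::expand_grid(
    outcome_class = c("reward", "penalty"), species = c("hbo", "hbd"),
    t_rel = t_rel)
  truth$value <- purrr::pmap_dbl(truth, function(outcome_class, species, t_rel) {
    p <- hrf[hrf$species == species & hrf$outcome_class == outcome_class, ]
    v <- hrf_kernel(t_rel - 8, p$dip_amplitude, p$dip_latency_s,
                    p$peak_amplitude, p$peak_latency_s, p$return_tau_s)
    if (cued) v <- v + anticipatory_wave(t_rel, 8, p$anticipatory_amplitude)
    v
  })

  structure(list(
    od = od, events = events, channels = channels,
    meta = list(sample_rate_hz = fs, n_trials = n_trials,
                reward_fraction = reward_fraction, cued = cued,
                color_scheme = color_scheme, seed = as.integer(seed),
                iti_mean_s = iti_mean_s, iti_min_s = iti_min_s,
                uncued_mean_s = uncued_mean_s, uncued_min_s = uncued_min_s,
                artifact_rate = artifact_rate,
                extinction = em, noise = noise, hrf = hrf),
    ground_truth = list(class_means = tibble::as_tibble(truth),
                        clean_conc = tibble::tibble(
                          time_s = time_s, d_hbd = conc[, "hbd"],
                          d_hbo = conc[, "hbo"]),
                        gains = gains)
  ), class = "nirs_session")
}

#' @export
print.nirs_session <- function(x, ...) {
  cat("<nirs_session>", x$meta$n_trials, "trials,",
      nrow(x$channels), "channels,",
      sprintf("%.1f s at %g Hz", max(x$od$time_s), x$meta$sample_rate_hz),
      if (x$meta$cued) "(cued)\n" else "(uncued)\n")
  invisible(x)
}

#' Place sham (idle-baseline) events in quiet periods of a session
#'
#' Samples `n` pseudo-event times whose full peri-event windows (10 s
#' baseline through 15 s post-outcome) do not overlap any real trial window,
#' giving idle-baseline "trials" against which real events can be classified.
#' Sham events carry `outcome_class = "baseline"`.
#'
#' @param session A `nirs_session`.
#' @param n Number of sham events.
#' @param seed Integer seed.
#' @param pre_s,post_s Extent of the protected peri-event window around a
#'   (virtual) cue onset, seconds.
#'
#' @return A tibble of sham events in the same shape as `session$events`.
#' @export
make_sham_events <- function(session, n, seed, pre_s = 10, post_s = 23) {
  stopifnot(inherits(session, "nirs_session"))
  if (n == 0) return(session$events[0, ])
  set.seed(as.integer(seed))
  fs <- session$meta$sample_rate_hz
  t_max <- max(session$od$time_s)
  real <- cbind(session$events$cue_onset_s - pre_s,
                session$events$outcome_onset_s + 15)
  cand <- seq(pre_s, t_max - post_s, by = 1 / fs)
  ok <- vapply(cand, function(t) {
    all(t + post_s < real[, 1] | t - pre_s > real[, 2])
  }, logical(1))
  cand <- cand[ok]
  chosen <- numeric(0)
  cand <- sample(cand)
  for (t in cand) {
    if (length(chosen) == n) break
    if (all(abs(t - chosen) >= pre_s + post_s)) chosen <- c(chosen, t)
  }
  if (length(chosen) < n) {
    stop("insufficient quiet time: only ", length(chosen),
         " non-overlapping sham windows available, ", n, " requested")
  }
  chosen <- sort(chosen)
  tibble::tibble(
    trial_id = max(session$events$trial_id) + seq_len(n),
    cue_onset_s = chosen,
    outcome_onset_s = chosen + if (session$meta$cued) 8 else 0,
    outcome_class = "baseline", cue_color = NA_character_,
    cued = session$meta$cued, artifact_tag = FALSE
  )
}
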