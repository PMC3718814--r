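# Shared fixtures, built once per test run.

quiet_noise <- function(...) {
  noise_params(white_sd = 0, drift_coeff = 0, cardiac_amp = 0, resp_amp = 0,
               meyer_amp = 0, gain_jitter_sd = 0, trial_amp_sd = 0,
               artifact_amp = 0, ...)
}

# Narrow-kernel response set whose tails die out within ~20 s, so that with
# long inter-trial intervals consecutive trials do not overlap (needed for
# exact forward/inverse identity checks).
sharp_hrf <- function() {
  hrf_params(data.frame(
    outcome_class = rep(c("reward", "penalty"), each = 2),
    species = rep(c("hbo", "hbd"), 2),
    dip_amplitude = c(0.25, 0.4, 0.5, 0.4),
    dip_latency_s = c(1.5, 3, 2, 3),
    peak_amplitude = c(0.9, 0, 0.1, 0),
    peak_latency_s = c(6, 8, 6, 8),
    return_tau_s = c(2.5, 2, 2.5, 2),
    anticipatory_amplitude = c(0.2, 0, -0.1, 0)))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default-condition session and its peri-event waveforms. 120 trials: the
# decoding protocol pools trials across sessions, and hold-one-out
# cross-validation needs enough trials that the held-out class imbalance
# (n-1 vs n in training) stays negligible.
default_peri <- function() {
  cached("default_peri", {
    s <- generate_session(n_trials = 120, seed = 101)
    h <- process_session(s)
    extract_peri_event(h)
  })
}

# Mean held-out accuracy over several label shuffles (the per-shuffle
# spread is overdispersed relative to binomial because slow physiological
# noise is shared between temporally adjacent trials).
shuffled_accuracy <- function(peri, n_shuffles = 10, n_rounds = 60,
                              seed = 900) {
  f0 <- build_features(peri, tau_s = 15)
  mean(sapply(seq_len(n_shuffles), function(k) {
    f <- f0
    set.seed(seed + k)
    f$label <- sample(f$label)
    f$y <- ifelse(f$label == "reward", 1, -1)
    jackknife_cv(f, n_rounds = n_rounds, seed = seed + 100 + k)$overall_accuracy
  }))
}

rel_l2 <- function(est, truth) {
  sqrt(sum((est - truth)^2) / sum(truth^2))
}
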