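test_that("identical config and seed give bit-identical sessions", {
  a <- generate_session(n_trials = 8, seed = 7)
  b <- generate_session(n_trials = 8, seed = 7)
  expect_identical(a$od, b$od)
  expect_identical(a$events, b$events)
  c <- generate_session(n_trials = 8, seed = 8)
  expect_false(identical(a$od, c$od))
})

test_that("cued trials have exactly 8 s between cue and outcome", {
  s <- generate_session(n_trials = 15, seed = 2)
  expect_equal(s$events$outcome_onset_s - s$events$cue_onset_s,
               rep(8, 15))
  expect_true(all(diff(s$events$cue_onset_s) > 0))
  expect_true(all(s$events$outcome_onset_s + 15 <= max(s$od$time_s)))
})

test_that("uncued deliveries respect the 40 s minimum spacing", {
  s <- generate_session(n_trials = 20, cued = FALSE, seed = 3)
  gaps <- diff(s$events$outcome_onset_s)
  expect_true(all(gaps >= 40))
  expect_equal(s$events$cue_onset_s, s$events$outcome_onset_s)
})

test_that("zero noise and zero response amplitudes give flat absorbance", {
  flat <- hrf_params()
  num <- c("dip_amplitude", "peak_amplitude", "anticipatory_amplitude")
  flat[num] <- lapply(flat[num], function(x) x * 0)
  s <- generate_session(n_trials = 4, hrf = flat, noise = quiet_noise(),
                        seed = 5)
  od <- as.matrix(s$od[-1])
  expect_true(all(od == 0))
})

test_that("realized reward fraction lies in the binomial 99% CI", {
  s <- generate_session(n_trials = 200, reward_fraction = 0.5, seed = 11)
  n_rew <- sum(s$events$outcome_class == "reward")
  ci <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(n_rew, ci[1])
  expect_lte(n_rew, ci[2])
})

test_that("color scheme maps cue colors to outcomes, and reverses", {
  s <- generate_session(n_trials = 30, seed = 4, color_scheme = "standard")
  expect_true(all(s$events$cue_color[s$events$outcome_class == "reward"] ==
                    "blue"))
  r <- generate_session(n_trials = 30, seed = 4, color_scheme = "reversed")
  expect_true(all(r$events$cue_color[r$events$outcome_class == "reward"] ==
                    "red"))
})

test_that("oscillatory noise components peak at their configured frequency", {
  for (cfg in list(c(2.0, "cardiac"), c(0.6, "resp"), c(0.1, "meyer"))) {
    f0 <- as.numeric(cfg[1])
    np <- quiet_noise()
    np[[paste0(cfg[2], "_amp")]] <- 1
    flat <- hrf_params()
    num <- c("dip_amplitude", "peak_amplitude", "anticipatory_amplitude")
    flat[num] <- lapply(flat[num], function(x) x * 0)
    s <- generate_session(n_trials = 10, hrf = flat, noise = np, seed = 6)
    x <- s$od$S1_D1_760
    n <- length(x)
    p <- Mod(fft(x - mean(x)))^2
    f <- (seq_len(n) - 1) * 6 / n
    half <- seq_len(floor(n / 2))
    f_peak <- f[half][which.max(p[half])]
    expect_lt(abs(f_peak - f0), 6 / n + 1e-9)  # within one frequency bin
  }
})

test_that("dead channels carry no stimulus-locked signal", {
  s <- generate_session(n_trials = 6, seed = 9,
                        noise = noise_params(dead_channel_ids = 2))
  dead <- s$od$S1_D2_760
  live <- s$od$S1_D1_760
  # live channel correlates with the embedded clean signal, dead does not
  clean <- forward_mbll(s$ground_truth$clean_conc[c("d_hbd", "d_hbo")],
                        s$meta$extinction)$da_760
  expect_gt(abs(cor(live, clean)), 0.3)
  expect_lt(abs(cor(dead, clean)), 0.2)
})

test_that("sham events are placed only in quiet periods", {
  s <- generate_session(n_trials = 6, seed = 12, iti_mean_s = 120,
                        iti_min_s = 80)
  expect_equal(nrow(make_sham_events(s, 0, seed = 1)), 0)
  sham <- make_sham_events(s, 4, seed = 1)
  expect_equal(nrow(sham), 4)
  expect_true(all(sham$outcome_class == "baseline"))
  for (i in seq_len(nrow(sham))) {
    w <- c(sham$cue_onset_s[i] - 10, sham$cue_onset_s[i] + 23)
    real <- cbind(s$events$cue_onset_s - 10, s$events$outcome_onset_s + 15)
    expect_true(all(w[2] < real[, 1] | w[1] > real[, 2]))
  }
})

test_that("requesting more shams than quiet slots errors informatively", {
  s <- generate_session(n_trials = 10, seed = 13)  # default busy schedule
  expect_error(make_sham_events(s, 50, seed = 1), "insufficient quiet time")
})

test_that("noise-free sessions are recovered exactly by the unfiltered chain", {
  s <- generate_session(n_trials = 12, hrf = sharp_hrf(),
                        noise = quiet_noise(), seed = 3,
                        iti_mean_s = 120, iti_min_s = 80)
  h <- process_session(s, filter = FALSE, snr_threshold = 0)
  peri <- extract_peri_event(h)
  cm <- dplyr::summarise(peri, value = mean(value),
                         .by = c("label", "species", "t_rel"))
  m <- dplyr::inner_join(
    cm[cm$species != "hbtot", ], s$ground_truth$class_means,
    by = c(label = "outcome_class", "species", "t_rel"),
    suffix = c("_est", "_true"))
  expect_equal(nrow(m), 2 * 2 * 139)
  expect_lt(rel_l2(m$value_est, m$value_true), 1e-6)
})

test_that("band-pass filtering preserves the response shape approximately", {
  s <- generate_session(n_trials = 12, hrf = sharp_hrf(),
                        noise = quiet_noise(), seed = 3,
                        iti_mean_s = 120, iti_min_s = 80)
  h <- process_session(s, filter = TRUE, snr_threshold = 0)
  peri <- extract_peri_event(h)
  cm <- dplyr::summarise(peri, value = mean(value),
                         .by = c("label", "species", "t_rel"))
  m <- dplyr::inner_join(
    cm[cm$species != "hbtot", ], s$ground_truth$class_means,
    by = c(label = "outcome_class", "species", "t_rel"),
    suffix = c("_est", "_true"))
  expect_lt(rel_l2(m$value_est, m$value_true), 0.2)
})

test_that("session round-trips through the on-disk CSV/JSON/YAML triplet", {
  s <- generate_session(n_trials = 4, seed = 21)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  expect_true(all(file.exists(file.path(
    dir, c("session.csv", "events.json", "meta.yaml")))))
  r <- read_session(dir)
  expect_equal(as.data.frame(r$od), as.data.frame(s$od), tolerance = 1e-12)
  expect_equal(r$events$outcome_class, s$events$outcome_class)
  expect_equal(r$meta$extinction$E, s$meta$extinction$E)
})
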