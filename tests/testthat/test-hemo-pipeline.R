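test_that("band-pass removes DC, passes 0.1 Hz, attenuates 2 Hz", {
  t <- seq(0, 1000, by = 1 / 6)
  # the 0.01 Hz edge has a ~100 s time constant; trim generously
  trim <- (300 * 6):(length(t) - 300 * 6)
  dc <- bandpass(rep(2, length(t)))
  expect_lt(max(abs(dc[trim])), 1e-3 * 2)
  tone <- bandpass(sin(2 * pi * 0.1 * t))
  amp <- max(abs(tone[trim]))
  expect_gt(amp, 0.9)
  expect_lt(amp, 1.1)
  fast <- bandpass(sin(2 * pi * 2.0 * t))
  expect_lt(max(abs(fast[trim])), 0.1)
})

test_that("band-pass rejects invalid bands and too-short input", {
  expect_error(bandpass(rnorm(100), low_hz = 0), "0 < low_hz")
  expect_error(bandpass(rnorm(100), high_hz = 4), "fs/2")
  expect_error(bandpass(rnorm(10)), "too short")
})

test_that("SNR rejection flags white-noise channels and keeps clean ones", {
  s <- generate_session(n_trials = 10, seed = 31,
                        noise = noise_params(dead_channel_ids = 3))
  mask <- snr_reject(s)
  expect_false(mask$keep[3])
  expect_true(all(mask$keep[-3]))
  # threshold 0 keeps everything
  expect_true(all(snr_reject(s, threshold = 0)$keep))
  # clean noise-free session: all channels kept at the default threshold
  clean <- generate_session(n_trials = 6, noise = quiet_noise(), seed = 32)
  expect_true(all(snr_reject(clean)$keep))
  # sufficiently high threshold rejects everything, with advice
  expect_error(snr_reject(s, threshold = 1e9), "review the threshold")
})

test_that("baseline referencing zeroes the baseline window", {
  od <- tibble::tibble(time_s = seq(0, 30, by = 1 / 6))
  od$ch <- 0.5                                  # constant channel
  out <- baseline_reference(od, cue_onset_s = 15)
  expect_true(all(abs(out$ch) < 1e-12))
  # step of +0.01 at the cue
  od$ch <- ifelse(od$time_s >= 15, 0.51, 0.50)
  out <- baseline_reference(od, cue_onset_s = 15)
  expect_equal(unique(out$ch[od$time_s < 15]), 0)
  expect_equal(unique(out$ch[od$time_s >= 15]), 0.01)
  expect_lt(abs(mean(out$ch[od$time_s >= 5 & od$time_s < 15])), 1e-12)
  expect_error(baseline_reference(od, cue_onset_s = 0), "baseline window")
})

test_that("channel averaging is the unweighted mean and hbtot the sum", {
  df <- tidyr::expand_grid(channel = c("a", "b"), time_s = 1:5)
  df$d_hbo <- ifelse(df$channel == "a", 1, -1)
  df$d_hbd <- ifelse(df$channel == "a", 2, 4)
  one <- average_channels(df, "a")
  expect_equal(one$d_hbo, rep(1, 5))
  both <- average_channels(df, c("a", "b"))
  expect_equal(both$d_hbo, rep(0, 5))            # x and -x cancel
  expect_equal(both$d_hbd, rep(3, 5))
  expect_equal(both$d_hbtot, both$d_hbo + both$d_hbd)
  expect_error(average_channels(df, character()), "empty")
})

test_that("peri-event extraction yields the exact sampling grid", {
  peri <- default_peri()
  # 23 s window at 6 Hz: 139 samples per trial and species
  expect_equal(length(unique(peri$t_rel)), 139)
  expect_equal(sort(unique(peri$species)), c("hbd", "hbo", "hbtot"))
  counts <- dplyr::count(peri, trial_id, species)
  expect_true(all(counts$n == 139))
  # labels preserved in trial order
  lab <- dplyr::distinct(peri[c("trial_id", "label")])
  expect_equal(lab$trial_id, sort(lab$trial_id))
})

test_that("empty event tables give an empty tensor without error", {
  s <- generate_session(n_trials = 4, seed = 33)
  h <- process_session(s, snr_threshold = 0)
  out <- extract_peri_event(h, events = s$events[0, ])
  expect_equal(nrow(out), 0)
})

test_that("pipeline is linear: scaling OD scales concentrations", {
  s <- generate_session(n_trials = 5, seed = 34)
  s3 <- s
  for (col in setdiff(names(s3$od), "time_s")) {
    s3$od[[col]] <- 3 * s3$od[[col]]
  }
  h1 <- process_session(s, snr_threshold = 0)
  h3 <- process_session(s3, snr_threshold = 0)
  expect_equal(h3$d_hbo, 3 * h1$d_hbo, tolerance = 1e-9)
  expect_equal(h3$d_hbd, 3 * h1$d_hbd, tolerance = 1e-9)
})

test_that("hemo series satisfies d_hbtot = d_hbo + d_hbd", {
  s <- generate_session(n_trials = 5, seed = 35)
  h <- process_session(s, snr_threshold = 0)
  expect_lt(max(abs(h$d_hbtot - (h$d_hbo + h$d_hbd))), 1e-12)
})

test_that("Welch statistics match the textbook formula", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  peri <- tibble::tibble(
    trial_id = 1:8, t_rel = 0, species = "hbo",
    value = c(x, y),
    label = rep(c("reward", "penalty"), each = 4), tag = FALSE)
  class(peri) <- c("peri_event_df", class(peri))
  gs <- group_stats(peri)
  # hand-evaluated Welch t and Welch-Satterthwaite df
  se2 <- var(x) / 4 + var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(gs$t, t_hand, tolerance = 1e-12)
  expect_equal(gs$p, p_hand, tolerance = 1e-12)
  expect_equal(gs$mean1, 2.5)
  expect_equal(gs$sem1, sd(x) / 2, tolerance = 1e-12)
  expect_equal(gs$group1, "reward")
})

test_that("identical groups give t = 0 and p = 1 at every timestep", {
  v <- rnorm(10)
  peri <- tibble::tibble(
    trial_id = rep(1:4, each = 10),
    t_rel = rep(seq(0, 1.5, by = 1 / 6), 4),
    species = "hbo",
    value = rep(v, 4),
    label = rep(c("reward", "penalty"), each = 20), tag = FALSE)
  class(peri) <- c("peri_event_df", class(peri))
  gs <- group_stats(peri)
  expect_true(all(gs$t == 0))
  expect_true(all(gs$p == 1))
  expect_true(all(!gs$significant))
})

test_that("groups with fewer than 2 trials are rejected", {
  peri <- tibble::tibble(trial_id = 1:3, t_rel = 0, species = "hbo",
                         value = 1:3,
                         label = c("reward", "reward", "penalty"),
                         tag = FALSE)
  class(peri) <- c("peri_event_df", class(peri))
  expect_error(group_stats(peri), "at least 2 trials")
})

test_that("default synthetic contrast yields significant post-outcome HbO", {
  gs <- group_stats(default_peri())
  hbo_post <- gs[gs$species == "hbo" & gs$t_rel > 8, ]
  expect_gt(sum(hbo_post$significant), 0)
  # and the reward mean exceeds the penalty mean around the HbO peak
  pk <- hbo_post[hbo_post$t_rel > 12 & hbo_post$t_rel < 16, ]
  expect_true(all(pk$mean1 > pk$mean2))
})

test_that("label shuffling brings the false-positive rate near alpha", {
  peri <- default_peri()
  labs <- dplyr::distinct(peri[c("trial_id", "label")])
  set.seed(99)
  rates <- replicate(30, {
    perm <- labs
    perm$label <- sample(perm$label)
    shuf <- dplyr::select(peri, -"label")
    shuf <- dplyr::left_join(shuf, perm, by = "trial_id")
    class(shuf) <- c("peri_event_df", class(shuf))
    gs <- group_stats(shuf)
    mean(gs$significant[gs$species == "hbo"])
  })
  expect_gt(mean(rates), 0.01)
  expect_lt(mean(rates), 0.12)
})

test_that("Bonferroni correction only reduces significance calls", {
  gs_raw <- group_stats(default_peri())
  gs_bon <- group_stats(default_peri(), correction = "bonferroni")
  expect_lte(sum(gs_bon$significant), sum(gs_raw$significant))
  expect_true(all(gs_bon$p >= gs_raw$p))
})
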