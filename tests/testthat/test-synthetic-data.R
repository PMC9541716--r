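test_that("fractal noise generator hits its target scaling exponent", {
  # reduced seed count vs the calibration target (20 per exponent) to keep
  # the default run fast; the full 50-seed calibration runs in acceptance
  targets <- c(0.5, 0.76, 1.0, 1.5)
  set.seed(101)
  for (a in targets) {
    est <- mean(replicate(20, dfa(generate_fractal_noise(512, a))$alpha))
    expect_lt(abs(est - a), 0.1)
  }
})

test_that("fractal noise respects its contract", {
  x <- generate_fractal_noise(512, 1.0, sd = 0.3, seed = 5)
  expect_length(x, 512)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sd(x), 0.3, tolerance = 1e-12)
  expect_error(generate_fractal_noise(8, 1.0), ">= 16")
  expect_error(generate_fractal_noise(512, 2.0), "alpha_target")
})

test_that("deterministic single-focus clock beats at exactly the base period", {
  cfg <- sim_config(n_foci = 1, noise_sd = 0, jitter_sd = 0,
                    duration = 20, seed = 1)
  gt <- simulate_beats(cfg)
  expect_true(all(abs(diff(gt$beat_times) - 0.8) < 1e-12))
  expect_true(all(gt$firing_focus == 1L))
})

test_that("faster of two fixed-period foci always fires; takeover moves the source", {
  cfg <- sim_config(n_foci = 2, base_period = c(0.9, 1.0), noise_sd = 0,
                    jitter_sd = 0, duration = 30, seed = 1)
  gt <- simulate_beats(cfg)
  expect_true(all(gt$firing_focus == 1L))
  s <- apply(gt$true_activation_times, 1,
             function(tt) unlist(fit_slowness(tt, cfg$layout)[c("s_x", "s_y")]))
  expect_lt(max(apply(s, 1, function(v) diff(range(v)))), 1e-10)

  # with noisy clocks both foci fire and the slowness vector jumps at switches
  cfg2 <- sim_config(n_foci = 2, noise_sd = 0.1, jitter_sd = 0,
                     duration = 120, seed = 3)
  gt2 <- simulate_beats(cfg2)
  expect_gt(length(unique(gt2$firing_focus)), 1L)
  s2 <- t(apply(gt2$true_activation_times, 1,
                function(tt) unlist(fit_slowness(tt, cfg2$layout)[c("s_x", "s_y")])))
  d <- sqrt(rowSums(diff(s2)^2))
  switch_beat <- diff(gt2$firing_focus) != 0
  expect_gt(min(d[switch_beat]), max(d[!switch_beat]))
})

test_that("simulated beat rate matches the base period within 2%", {
  cfg <- sim_config(n_foci = 1, noise_sd = 0.05, duration = 200, seed = 5)
  gt <- simulate_beats(cfg)
  expect_lt(abs(mean(1 / diff(gt$beat_times)) - 1.25) / 1.25, 0.02)
})

test_that("ground truth respects propagation bounds", {
  cfg <- sim_config(n_foci = 3, jitter_sd = 2e-4, duration = 60, seed = 9)
  gt <- simulate_beats(cfg)
  expect_true(all(diff(gt$beat_times) > 0))
  max_dist <- 2 * cfg$disc_radius
  spread_bound <- max_dist / cfg$conduction_velocity + 8 * cfg$jitter_sd
  spread <- apply(gt$true_activation_times, 1, function(x) diff(range(x)))
  expect_lt(max(spread), spread_bound)
})

test_that("noiseless synthesis round-trips every activation within one sample", {
  cfg <- clean_sim(duration = 20, seed = 3)
  gt <- simulate_beats(cfg)
  rec <- synthesize_electrograms(gt)
  ev <- detect_recording(rec, filter_config(lowpass_cutoff = NULL))
  expect_equal(nrow(ev), length(gt$true_activation_times))
  bs <- quiet_cluster(ev)
  expect_equal(nrow(bs$beats), length(gt$beat_times))
  err <- abs(bs$times - gt$true_activation_times[, colnames(bs$times)])
  expect_lt(max(err), 1 / cfg$sampling_rate + 1e-12)
})

test_that("an empty ground truth yields a flat recording with no detections", {
  cfg <- clean_sim(duration = 5, seed = 1)
  gt <- simulate_beats(cfg)
  gt$true_activation_times <- gt$true_activation_times[0, , drop = FALSE]
  gt$beat_times <- numeric(0)
  rec <- synthesize_electrograms(gt)
  expect_true(all(rec$signals == 0))
  ev <- detect_recording(rec, filter_config(lowpass_cutoff = NULL))
  expect_equal(nrow(ev), 0L)
})

test_that("overlapping templates 0.8 ms apart fuse to one weighted event", {
  cfg <- clean_sim(duration = 5, seed = 1)
  gt <- simulate_beats(cfg)
  # fractionated beat: second deflection 0.8 ms after the first on channel 1
  gt$true_activation_times <- matrix(c(1.0, 1.0008), 2, nrow(cfg$layout))
  gt$beat_times <- c(1.0, 1.0008)
  gt$fire_times <- gt$beat_times
  gt$firing_focus <- c(1L, 1L)
  expect_warning(rec <- synthesize_electrograms(gt), "overlap")
  cfgf <- filter_config(lowpass_cutoff = NULL)
  y <- condition_signal(rec$signals[1, ], rec$sampling_rate, cfgf)
  raw <- detect_activations(y, rec$sampling_rate, cfgf)
  fused <- fuse_fractionated(raw, cfgf$fusion_window)
  expect_gt(nrow(raw), 1L)
  expect_equal(nrow(fused), 1L)
  expect_gt(fused$time, 1.0 - 1e-4)
  expect_lt(fused$time, 1.0008 + 1e-4)
  expect_equal(fused$weight, sum(raw$weight))
})

test_that("focus positions are constrained to the disc boundary", {
  expect_error(sim_config(n_foci = 1, focus_positions = rbind(c(0.1, 0.1))),
               "disc boundary")
  cfg <- sim_config(n_foci = 2)
  r <- sqrt(rowSums(cfg$focus_positions^2))
  expect_equal(r, rep(0.4, 2), tolerance = 1e-12)
})

test_that("stretch protocol events are laid out as specified", {
  sp <- stretch_protocol(hold_duration = 60, release_duration = 120,
                         n_repeats = 4, motor_time = 2, start_offset = 10)
  ev <- protocol_events(sp)
  expect_equal(nrow(ev), 8L)
  expect_equal(ev$kind, rep(c("stretch", "release"), 4))
  expect_equal(ev$motor_start[1:2], c(10, 70))
  expect_true(all(ev$motor_end - ev$motor_start == 2))
  # accelerations: beats bunch up right after each motor movement
  cfg <- sim_config(n_foci = 1, noise_sd = 0, jitter_sd = 0, duration = 200,
                    stretch_protocol = stretch_protocol(
                      hold_duration = 30, release_duration = 60, n_repeats = 2,
                      rate_gain_stretch = 2, decay_tau = 2, start_offset = 20),
                    seed = 2)
  gt <- simulate_beats(cfg)
  ibi <- diff(gt$beat_times)
  at <- gt$beat_times[-1]
  during <- ibi[at > 21 & at < 23]
  baseline <- ibi[at > 10 & at < 20]
  expect_lt(min(during), 0.6 * min(baseline))
})
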