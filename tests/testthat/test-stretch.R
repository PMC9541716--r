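test_that("motor pulses are parsed to events with sample accuracy", {
  rate <- 1000
  ch <- numeric(30 * rate)
  starts <- c(2, 8, 14, 20)  # alternating stretch/release
  for (s in starts) ch[(s * rate + 1):((s + 2) * rate + 1)] <- 5
  ev <- parse_motor_events(ch, rate)
  expect_equal(nrow(ev), 4L)
  expect_equal(ev$kind, c("stretch", "release", "stretch", "release"))
  expect_equal(ev$motor_start, starts, tolerance = 1 / rate)
  expect_equal(ev$motor_end - ev$motor_start, rep(2, 4),
               tolerance = 2 / rate)

  expect_equal(nrow(parse_motor_events(numeric(0), rate)), 0L)
  expect_equal(nrow(parse_motor_events(numeric(1000), rate)), 0L)
})

test_that("simulator event channel round-trips through the parser", {
  sp <- stretch_protocol(hold_duration = 15, release_duration = 20,
                         n_repeats = 3, motor_time = 1.5, start_offset = 5)
  cfg <- clean_sim(duration = 115, seed = 31, stretch_protocol = sp)
  gt <- simulate_beats(cfg)
  rec <- synthesize_electrograms(gt)
  ev <- parse_motor_events(rec$event_channel, rec$sampling_rate)
  expect_equal(nrow(ev), 6L)
  expect_equal(ev$kind, gt$event_times$kind)
  expect_equal(ev$motor_start, gt$event_times$motor_start,
               tolerance = 1 / rec$sampling_rate)
  expect_equal(ev$motor_end, gt$event_times$motor_end,
               tolerance = 1 / rec$sampling_rate)
})

test_that("a constant beat rate epoch-averages to a flat normalized trace", {
  ibr <- resample_ibr(seq(0, 100, by = 1), dt = 0.5)  # 1 Hz throughout
  ev <- data.frame(kind = c("stretch", "release"),
                   motor_start = c(30, 60), motor_end = c(32, 62))
  ea <- epoch_average(ibr, ev, "stretch")
  expect_true(all(abs(ea$normalized - 1) < 1e-12, na.rm = TRUE))
  expect_equal(ea$mean_peak, 1)
  expect_equal(ea$peak_time, 1.75)  # 2-s motor, 0.5-s bins -> bin [1.5, 2)
})

test_that("epoch peak bin index equals ceil(motor_duration / dt)", {
  ibr <- resample_ibr(seq(0, 200, by = 0.8), dt = 0.5)
  for (mt in c(2.0, 1.5)) {
    ev <- data.frame(kind = "stretch", motor_start = 50,
                     motor_end = 50 + mt)
    ea <- epoch_average(ibr, ev, "stretch")
    expect_equal(ea$peak_time, (ceiling(mt / 0.5) - 0.5) * 0.5)
  }
})

test_that("simulated stretch protocol shows the transient rate surge and decay", {
  sp <- stretch_protocol(hold_duration = 30, release_duration = 40,
                         n_repeats = 5, rate_gain_stretch = 2,
                         rate_gain_release = 1.4, decay_tau = 2,
                         start_offset = 20)
  cfg <- sim_config(n_foci = 2, noise_sd = 0.02, duration = 380,
                    stretch_protocol = sp, seed = 22)
  gt <- simulate_beats(cfg)
  ibr <- resample_ibr(gt$beat_times)
  ea <- epoch_average(ibr, gt$event_times, "stretch")
  er <- epoch_average(ibr, gt$event_times, "release")
  # peak approaches the programmed gain (attenuated by the motor ramp and
  # 0.5-s binning) and exceeds the weaker release response
  expect_gt(ea$mean_peak, 1.5)
  expect_lt(ea$mean_peak, 2.1)
  expect_gt(ea$mean_peak, er$mean_peak)
  expect_gt(er$mean_peak, 1)
  # acceleration dissipates: trace back within 5% of baseline by t = +8 s
  late <- ea$mean_trace[ea$time_axis >= 8 & ea$time_axis < 15]
  expect_true(all(abs(late - 1) < 0.05))
  # normalization invariance: scaling the whole IBR leaves everything fixed
  ibr2 <- ibr; ibr2$rate <- 3.7 * ibr2$rate
  ea2 <- epoch_average(ibr2, gt$event_times, "stretch")
  expect_equal(ea2$normalized, ea$normalized, tolerance = 1e-12)
  expect_equal(ea2$mean_peak, ea$mean_peak, tolerance = 1e-12)
  # averaging consistency
  expect_equal(ea$mean_trace, colMeans(ea$normalized, na.rm = TRUE),
               tolerance = 1e-12)
})

test_that("repeats without a usable baseline are excluded with a warning", {
  ibr <- resample_ibr(seq(40, 100, by = 1), dt = 0.5)  # starts at t = 40
  # first repeat's pre-window [30, 35) lies entirely before the first beat
  ev <- data.frame(kind = c("stretch", "stretch"),
                   motor_start = c(35, 70), motor_end = c(37, 72))
  expect_warning(ea <- epoch_average(ibr, ev, "stretch"), "baseline")
  expect_equal(ea$n_repeats, 1L)
  expect_error(suppressWarnings(
    epoch_average(ibr, ev[1, , drop = FALSE], "stretch")), "usable")
  expect_error(epoch_average(ibr, ev, "release"), "no 'release'")
})

test_that("areal strain reproduces the substrate-geometry arithmetic", {
  expect_equal(areal_strain(0.05, 0), 5)
  expect_equal(areal_strain(0.02, 0.02), 4.04)
  expect_equal(areal_strain(0, 0), 0)
  expect_error(areal_strain(-1, 0), "> -1")
})

test_that("cross-preparation summary gates on normality and reproduces the printed p", {
  set.seed(33)
  v <- 1 + exp(rnorm(25, 0, 1.5))  # 25 fold-changes all above 1: log-normal
  s <- summarize_across_preparations(v, null_value = 1)
  expect_equal(s$test, "Wilcoxon signed rank")
  expect_equal(s$p, 1.23e-5, tolerance = 0.005)
  expect_equal(s$median, median(v))

  # symmetric about the null: p near 1
  set.seed(34)
  d <- rnorm(25, 0, 0.2)
  v2 <- 1 + c(d, -d)[1:25]
  s2 <- summarize_across_preparations(v2, null_value = 1)
  expect_gt(s2$p, 0.3)

  # degenerate constant input keeps the summary but cannot test
  s3 <- summarize_across_preparations(c(2, 2, 2))
  expect_equal(s3$median, 2)
  expect_equal(unname(s3$iqr), c(2, 2))
  expect_true(is.na(s3$p))
})
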