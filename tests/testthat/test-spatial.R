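lay12 <- default_layout()

test_that("slowness fit equals the closed-form normal-equations solution", {
  set.seed(4)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    idx <- sample(12, n)
    t <- 0.01 + 0.02 * lay12$x_cm[idx] - 0.015 * lay12$y_cm[idx] +
      rnorm(n, 0, 5e-4)
    names(t) <- lay12$electrode[idx]
    got <- fit_slowness(t, lay12)
    want <- normal_eq_slowness(t, lay12$x_cm[idx], lay12$y_cm[idx])
    expect_equal(got$s_x, unname(want["s_x"]), tolerance = 1e-10)
    expect_equal(got$s_y, unname(want["s_y"]), tolerance = 1e-10)
    expect_equal(got$t0, unname(want["t0"]), tolerance = 1e-10)
  }
})

test_that("noiseless planar activation is fitted exactly", {
  t <- 0.005 + 0.0341 * lay12$x_cm
  names(t) <- lay12$electrode
  s <- fit_slowness(t, lay12)
  expect_equal(s$s_x, 0.0341, tolerance = 1e-12)
  expect_equal(s$s_y, 0, tolerance = 1e-12)
  expect_equal(s$residual_rms, 0, tolerance = 1e-12)
  expect_equal(s$norm, 0.0341, tolerance = 1e-12)

  # identical times everywhere: zero slowness
  t0 <- rep(0.01, 12); names(t0) <- lay12$electrode
  s0 <- fit_slowness(t0, lay12)
  expect_equal(s0$norm, 0, tolerance = 1e-12)
})

test_that("slowness fit recovers the truth under jitter (Monte Carlo)", {
  set.seed(8)
  n_rep <- 300
  est <- replicate(n_rep, {
    t <- 0.005 + 0.0341 * lay12$x_cm + rnorm(12, 0, 2e-4)
    names(t) <- lay12$electrode
    fit_slowness(t, lay12)$s_x
  })
  se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - 0.0341), 3 * se)
})

test_that("slowness fit errors on degenerate geometry and few electrodes", {
  t3 <- c(E1 = 0.1, E2 = 0.2, E3 = 0.3)
  expect_error(fit_slowness(t3, lay12), ">= 4")
  col_lay <- data.frame(electrode = paste0("C", 1:5),
                        x_cm = seq(0, 0.4, 0.1), y_cm = seq(0, 0.4, 0.1))
  tc <- seq(0, 0.01, length.out = 5); names(tc) <- col_lay$electrode
  expect_error(fit_slowness(tc, col_lay), "collinear")
})

test_that("slowness fit is rotation equivariant", {
  set.seed(5)
  t <- 0.01 + 0.03 * lay12$x_cm - 0.01 * lay12$y_cm + rnorm(12, 0, 1e-4)
  names(t) <- lay12$electrode
  s0 <- fit_slowness(t, lay12)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- as.matrix(lay12[, c("x_cm", "y_cm")]) %*% t(R)
  lay_rot <- data.frame(electrode = lay12$electrode,
                        x_cm = xy[, 1], y_cm = xy[, 2])
  s1 <- fit_slowness(t, lay_rot)
  rot <- R %*% c(s0$s_x, s0$s_y)
  expect_equal(c(s1$s_x, s1$s_y), as.numeric(rot), tolerance = 1e-10)
  expect_equal(s1$norm, s0$norm, tolerance = 1e-10)
})

test_that("velocity is the reciprocal-magnitude companion of slowness", {
  v <- slowness_to_velocity(c(0.0341, 0))
  expect_equal(v$speed, 1 / 0.0341)
  expect_equal(round(v$speed, 1), 29.3)
  expect_equal(round(slowness_to_velocity(c(0.0334, 0))$speed, 1), 29.9)
  # direction preserved
  v2 <- slowness_to_velocity(c(0.03, 0.04))
  expect_equal(atan2(v2$v_y, v2$v_x), atan2(0.04, 0.03))
  expect_equal(v2$speed, 20)
  expect_error(slowness_to_velocity(c(0, 0)), "undefined")
})

test_that("PCA of offset activation times captures planar-wave structure", {
  # rank-2 data: beats drawn from two orthogonal planar waves
  set.seed(6)
  waves <- rbind(0.03 * lay12$x_cm, 0.03 * lay12$y_cm)
  tm <- waves[sample(1:2, 60, replace = TRUE), ] +
    matrix(rep(runif(60, 1, 100), 12), 60)  # arbitrary beat offsets
  colnames(tm) <- lay12$electrode
  p <- pca_activation(tm)
  expect_equal(p$cumulative_two, 1, tolerance = 1e-9)
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-10)
  expect_true(all(diff(p$variance_fractions) <= 1e-12))
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)

  # pure i.i.d. jitter: variance spread far below the planar-wave case
  tm2 <- matrix(rnorm(300 * 12, 0, 5e-4), 300)
  colnames(tm2) <- lay12$electrode
  p2 <- pca_activation(tm2)
  expect_lt(p2$cumulative_two, 0.5)

  expect_error(pca_activation(tm[1:2, ]), ">= 3")
})

test_that("slowness entropy matches direct evaluation and its invariants", {
  # all vectors in one bin
  e0 <- slowness_entropy(rep(0.001, 5), rep(0.001, 5))
  expect_equal(e0$E, 0)
  expect_equal(e0$occupied_bins, 1L)

  # equal counts over 4 bins -> ln 4
  sx <- c(0.001, 0.006, 0.001, 0.006)
  sy <- c(0.001, 0.001, 0.006, 0.006)
  expect_equal(slowness_entropy(sx, sy)$E, log(4))

  # counts {2,1,1}
  e3 <- slowness_entropy(c(0.001, 0.002, 0.007, 0.012),
                         rep(0.001, 4))
  expect_equal(e3$E, -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(e3$E, 1.0397, tolerance = 1e-4)

  # permutation invariance; splitting a cluster cannot decrease E
  set.seed(9)
  sx <- runif(200, 0, 0.02); sy <- runif(200, 0, 0.02)
  perm <- sample(200)
  expect_equal(slowness_entropy(sx, sy)$E,
               slowness_entropy(sx[perm], sy[perm])$E)
  tight <- slowness_entropy(rep(0.001, 100), rep(0.001, 100))$E
  split <- slowness_entropy(c(rep(0.001, 50), rep(0.007, 50)),
                            rep(0.001, 100))$E
  expect_gte(split, tight)
})

test_that("interbeat slowness differences flag focus switches", {
  tab <- data.frame(beat = 1:4,
                    s_x = c(0.03, 0, 0.03, 0),
                    s_y = c(0, 0.03, 0, 0.03),
                    eligible = TRUE)
  d <- interbeat_slowness_diff(tab)
  expect_equal(d, rep(0.03 * sqrt(2), 3))

  # constant slowness -> zeros; ineligible beats drop pairs
  tab2 <- data.frame(beat = 1:4, s_x = 0.02, s_y = 0.01,
                     eligible = c(TRUE, TRUE, FALSE, TRUE))
  d2 <- interbeat_slowness_diff(tab2)
  expect_equal(d2, c(0, NA, NA))

  # simulated takeover: the largest jumps are exactly the switch beats
  cfg <- sim_config(n_foci = 2, noise_sd = 0.1, jitter_sd = 0,
                    duration = 100, seed = 13)
  gt <- simulate_beats(cfg)
  st <- t(apply(gt$true_activation_times, 1, function(tt)
    unlist(fit_slowness(tt, cfg$layout)[c("s_x", "s_y")])))
  tab3 <- data.frame(beat = seq_len(nrow(st)), s_x = st[, 1], s_y = st[, 2],
                     eligible = TRUE)
  d3 <- interbeat_slowness_diff(tab3)
  switches <- diff(gt$firing_focus) != 0
  expect_gt(sum(switches), 0)
  expect_gt(min(d3[switches]), max(d3[!switches]))
})
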