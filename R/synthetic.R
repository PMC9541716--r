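#' Fractal (power-law) noise by spectral synthesis
#'
#' Generates a zero-mean series whose power spectral density is proportional
#' to 1/f^beta with beta = 2*alpha - 1, so that its detrended-fluctuation
#' exponent (see [dfa()]) equals `alpha_target`: alpha = 0.5 gives white
#' noise, alpha = 1 gives 1/f noise, alpha = 1.5 gives Brownian noise.
#' Construction: random-phase Hermitian spectrum with the target amplitude
#' law, inverse FFT, then rescaling to the requested standard deviation.
#'
#' @param length series length (>= 16).
#' @param alpha_target target scaling exponent, in \[0.3, 1.6\].
#' @param sd standard deviation of the output series.
#' @param seed optional integer seed (local to this call).
#' @return numeric vector of `length` values, zero mean, sd `sd`.
#' @examples
#' x <- generate_fractal_noise(512, alpha_target = 0.76, sd = 1, seed = 1)
#' dfa(x)$alpha
#' @export
generate_fractal_noise <- function(length, alpha_target, sd = 1, seed = NULL) {
  n <- as.integer(length)
  if (n < 16L) stop("'length' must be >= 16")
  if (!is.numeric(alpha_target) || alpha_target < 0.3 || alpha_target > 1.6)
    stop("'alpha_target' must lie in [0.3, 1.6]")
  if (!is.null(seed)) set.seed(seed)
  beta <- 2 * alpha_target - 1
  m <- n %/% 2L
  f <- (1:m) / n
  amp <- f^(-beta / 2)
  ph <- stats::runif(m, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  if (n %% 2L == 0L)  # Nyquist bin must be real
    spec[m] <- complex(modulus = amp[m], argument = 0)
  full <- complex(n)
  full[2:(m + 1L)] <- spec
  # Hermitian symmetry: X[n + 2 - j] = Conj(X[j])
  j <- 2:(if (n %% 2L == 0L) m else m + 1L)
  full[n + 2L - j] <- Conj(full[j])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (sd / s)
  x
}

#' Stretch/release protocol specification for the simulator
#'
#' Describes the repeated stretch-hold-release protocol: strain is applied by
#' linear motors over `motor_time` seconds, held for `hold_duration`, then
#' released (again taking `motor_time`) and left released for
#' `release_duration`. Both stretch and release transiently accelerate all
#' pacemaker foci by a gain that ramps up during the motor movement and then
#' decays exponentially with time constant `decay_tau`, so the acceleration
#' dissipates within roughly 4 time constants (~8 s at the default).
#'
#' @param hold_duration s between stretch motor start and release motor
#'   start (default 60, i.e. strain held for 1 min).
#' @param release_duration s from release motor start to the next stretch
#'   (default 120).
#' @param n_repeats number of stretch/release repetitions (default 5).
#' @param motor_time motor travel time in s (2.0 for uniaxial protocols,
#'   1.5 for biaxial).
#' @param rate_gain_stretch peak rate multiplier reached at the end of the
#'   stretch movement (> 1).
#' @param rate_gain_release same for release.
#' @param decay_tau s, exponential decay constant of the acceleration.
#' @param start_offset s of undisturbed baseline before the first stretch.
#' @return object of class `"stretch_protocol"`.
#' @export
stretch_protocol <- function(hold_duration = 60, release_duration = 120,
                             n_repeats = 5, motor_time = 2.0,
                             rate_gain_stretch = 2.0,
                             rate_gain_release = 1.4,
                             decay_tau = 2.0, start_offset = 10) {
  if (hold_duration + release_duration <= 0)
    stop("hold_duration + release_duration must be > 0")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (motor_time <= 0) stop("motor_time must be > 0")
  structure(list(hold_duration = hold_duration,
                 release_duration = release_duration,
                 n_repeats = n_repeats, motor_time = motor_time,
                 rate_gain_stretch = rate_gain_stretch,
                 rate_gain_release = rate_gain_release,
                 decay_tau = decay_tau, start_offset = start_offset),
            class = "stretch_protocol")
}

#' Table of motor events implied by a stretch protocol
#'
#' @param protocol a [stretch_protocol()].
#' @return data frame `kind` ("stretch"/"release"), `motor_start`,
#'   `motor_end` (s).
#' @export
protocol_events <- function(protocol) {
  stopifnot(inherits(protocol, "stretch_protocol"))
  cyc <- protocol$hold_duration + protocol$release_duration
  out <- lapply(seq_len(protocol$n_repeats) - 1L, function(r) {
    s0 <- protocol$start_offset + r * cyc
    r0 <- s0 + protocol$hold_duration
    data.frame(kind = c("stretch", "release"),
               motor_start = c(s0, r0),
               motor_end = c(s0, r0) + protocol$motor_time,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Rate gain g(t) applied to all foci: linear ramp to the event's gain
# during the motor movement, exponential decay afterwards; each new motor
# event restarts the modulation (by the time it does, ~30 s later, the
# previous decay is numerically dead).
rate_gain_at <- function(t, events, gains, decay_tau) {
  if (is.null(events) || nrow(events) == 0L) return(1)
  prior <- which(events$motor_start <= t)
  if (!length(prior)) return(1)
  i <- prior[length(prior)]
  g <- gains[[events$kind[i]]]
  if (t <= events$motor_end[i]) {
    frac <- (t - events$motor_start[i]) /
      (events$motor_end[i] - events$motor_start[i])
    1 + (g - 1) * frac
  } else {
    1 + (g - 1) * exp(-(t - events$motor_end[i]) / decay_tau)
  }
}

# Integral of g(u) du from 0 to t (closed form per event segment). Each
# focus clock advances at rate g(t) / period, so a cycle of intrinsic
# period P started at t0 fires at the t solving G(t) - G(t0) = P.
gain_integral_fn <- function(events, gains, decay_tau) {
  if (is.null(events) || nrow(events) == 0L) return(identity)
  s <- events$motor_start
  e <- events$motor_end
  g <- unlist(gains)[events$kind]
  nxt <- c(s[-1], Inf)  # each event is superseded at the next motor start
  function(t) {
    vapply(t, function(ti) {
      extra <- 0
      for (i in seq_along(s)) {
        tt <- min(ti, nxt[i])
        if (tt <= s[i]) break
        a <- min(tt, e[i])
        extra <- extra + (g[i] - 1) * (a - s[i])^2 / (2 * (e[i] - s[i]))
        if (tt > e[i])
          extra <- extra + (g[i] - 1) * decay_tau *
            (1 - exp(-(tt - e[i]) / decay_tau))
      }
      ti + extra
    }, numeric(1))
  }
}

#' Biphasic extracellular electrogram template parameters
#'
#' The unipolar electrogram of a passing wavefront: an initial positive
#' phase, a rapid downstroke (typically < 1 ms) and a slower negative
#' phase. The template is built from three half-cosine segments (rise,
#' downstroke, recovery), so its first derivative is negative only inside
#' the downstroke and has a single sharp minimum at the downstroke
#' midpoint, which defines the activation time.
#'
#' @param positive_width_ms duration of the positive rise phase.
#' @param downstroke_width_ms duration of the downstroke; must be < 1 ms.
#' @param negative_width_ms duration of the negative recovery phase
#'   (typically the longest).
#' @param amplitude lobe amplitude in signal units (12-bit style scale).
#' @return list of class `"egm_waveform"`.
#' @export
egm_waveform <- function(positive_width_ms = 3, downstroke_width_ms = 0.6,
                         negative_width_ms = 5, amplitude = 1000) {
  if (downstroke_width_ms >= 1)
    stop("downstroke_width_ms must be < 1 (sub-millisecond downstroke)")
  if (any(c(positive_width_ms, negative_width_ms, amplitude) <= 0))
    stop("waveform widths and amplitude must be > 0")
  structure(list(positive_width_ms = positive_width_ms,
                 downstroke_width_ms = downstroke_width_ms,
                 negative_width_ms = negative_width_ms,
                 amplitude = amplitude), class = "egm_waveform")
}

# Sampled template plus the index (1-based) of its centred-difference
# derivative minimum, so callers can align that sample with the true
# activation time exactly. Piecewise half-cosine segments keep the
# derivative >= 0 outside the downstroke (one detectable minimum) and make
# the minimum sharp enough that causal AC coupling does not move it off its
# sample.
waveform_template <- function(waveform, sampling_rate) {
  t1 <- waveform$positive_width_ms / 1e3
  wd <- waveform$downstroke_width_ms / 1e3
  t2 <- waveform$negative_width_ms / 1e3
  A <- waveform$amplitude
  half <- wd / 2
  k <- seq(-round((t1 + half) * sampling_rate),
           round((t2 + half) * sampling_rate))
  t <- k / sampling_rate
  w <- numeric(length(t))
  rise <- t >= -(half + t1) & t < -half
  w[rise] <- A * 0.5 * (1 - cos(pi * (t[rise] + half + t1) / t1))
  drop <- t >= -half & t <= half
  w[drop] <- A * cos(pi * (t[drop] + half) / wd)
  rec <- t > half & t <= half + t2
  w[rec] <- -A * 0.5 * (1 + cos(pi * (t[rec] - half) / t2))
  n <- length(w)
  dw <- (w[3:n] - w[1:(n - 2)]) * sampling_rate / 2
  list(values = w, center = which.min(dw) + 1L)
}

#' Simulator configuration
#'
#' Stated world of the synthetic recordings: a disc-shaped monolayer
#' (radius 0.4 cm) whose spontaneous beats originate from pacemaker foci on
#' the disc periphery. Each focus k carries a phase clock with instantaneous
#' period `base_period * exp(noise_k)`, where `noise_k` is fractal noise
#' with DFA exponent `noise_alpha`; at every cycle the focus reaching
#' threshold first fires and resets all clocks (mutual-entrainment
#' caricature), so the fastest focus drives the tissue and focus takeover
#' occurs when the leader transiently slows below a competitor. Excitation
#' propagates radially from the firing focus at `conduction_velocity`; a
#' stretch protocol, when given, multiplies all foci rates uniformly.
#'
#' @param n_foci number of peripheral pacemaker foci (>= 1; default 4).
#' @param layout electrode layout data frame (default [default_layout()]).
#' @param focus_positions optional matrix/data.frame of focus (x, y) in cm;
#'   defaults to `n_foci` points evenly spaced on the disc boundary. All
#'   positions must lie on the boundary (radius `disc_radius`).
#' @param base_period intrinsic cycle length in s; scalar or one value per
#'   focus (default 0.8).
#' @param noise_alpha target DFA exponent of the log-period noise
#'   (default 1, i.e. 1/f).
#' @param noise_sd sd of the log-period fluctuations (default 0.1).
#' @param common_mode_sd sd of a log-period component shared by all foci
#'   (default 0).
#' @param conduction_velocity cm/s (default 30).
#' @param jitter_sd s, sd of per-electrode activation-time jitter
#'   (default 0.5 ms).
#' @param sampling_rate Hz (default 10000).
#' @param waveform an [egm_waveform()].
#' @param noise_floor_sd sd of additive white noise in signal units
#'   (default 20, ~2% of the default amplitude).
#' @param baseline_drift `c(amplitude =, period_s =)` of a slow sinusoidal
#'   baseline per channel (default amplitude 100, period 2 s).
#' @param duration recording length in s.
#' @param takeover_enabled if `FALSE` only focus 1 is active, emulating the
#'   reduced spatial complexity seen when active contraction is inhibited.
#' @param stretch_protocol optional [stretch_protocol()].
#' @param quantize_12bit apply 12-bit quantization to the synthesized
#'   signals (off by default).
#' @param disc_radius culture disc radius in cm (default 0.4).
#' @param seed integer seed used by [simulate_beats()] and
#'   [synthesize_electrograms()].
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_foci = 4, layout = default_layout(),
                       focus_positions = NULL, base_period = 0.8,
                       noise_alpha = 1.0, noise_sd = 0.1,
                       common_mode_sd = 0, conduction_velocity = 30,
                       jitter_sd = 5e-4, sampling_rate = 10000,
                       waveform = egm_waveform(), noise_floor_sd = 20,
                       baseline_drift = c(amplitude = 100, period_s = 2),
                       duration = 120, takeover_enabled = TRUE,
                       stretch_protocol = NULL, quantize_12bit = FALSE,
                       disc_radius = 0.4, seed = NULL) {
  layout <- validate_layout(layout)
  if (n_foci < 1) stop("n_foci must be >= 1")
  if (is.null(focus_positions)) {
    ang <- 2 * pi * (seq_len(n_foci) - 1) / n_foci + pi / 7
    focus_positions <- cbind(x = disc_radius * cos(ang),
                             y = disc_radius * sin(ang))
  } else {
    focus_positions <- as.matrix(focus_positions)
    if (nrow(focus_positions) != n_foci)
      stop("focus_positions must have one row per focus")
    r <- sqrt(rowSums(focus_positions^2))
    if (any(abs(r - disc_radius) > 1e-6 * max(1, disc_radius)))
      stop("all focus positions must lie on the disc boundary (radius ",
           disc_radius, " cm)")
  }
  base_period <- rep_len(base_period, n_foci)
  if (any(base_period <= 0)) stop("base_period must be > 0")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (!inherits(waveform, "egm_waveform")) stop("'waveform' must be an egm_waveform")
  if (!is.null(stretch_protocol) &&
      !inherits(stretch_protocol, "stretch_protocol"))
    stop("'stretch_protocol' must be a stretch_protocol object")
  structure(list(n_foci = n_foci, layout = layout,
                 focus_positions = focus_positions,
                 base_period = base_period, noise_alpha = noise_alpha,
                 noise_sd = noise_sd, common_mode_sd = common_mode_sd,
                 conduction_velocity = conduction_velocity,
                 jitter_sd = jitter_sd, sampling_rate = sampling_rate,
                 waveform = waveform, noise_floor_sd = noise_floor_sd,
                 baseline_drift = baseline_drift, duration = duration,
                 takeover_enabled = takeover_enabled,
                 stretch_protocol = stretch_protocol,
                 quantize_12bit = quantize_12bit,
                 disc_radius = disc_radius, seed = seed),
            class = "sim_config")
}

#' Simulate beats from competing pacemaker foci
#'
#' Runs the winner-resets-all phase-clock model of [sim_config()] and
#' returns the ground truth: per-beat firing focus, firing instants, the
#' per-beat, per-electrode true activation times (focus-to-electrode
#' distance over conduction velocity, plus Gaussian jitter), and the motor
#' event table of the stretch protocol, if any.
#'
#' @param config a [sim_config()].
#' @return object of class `"ground_truth"` with elements `beat_times`
#'   (mean activation time per beat, s), `firing_focus`, `fire_times`,
#'   `true_activation_times` (beats x electrodes matrix), `event_times`
#'   (data frame or NULL), `noise_series` (foci x cycles matrix of
#'   log-period noise) and `config`.
#' @export
simulate_beats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_foci <- config$n_foci
  active <- if (config$takeover_enabled) seq_len(n_foci) else 1L
  n_max <- ceiling(config$duration / min(config$base_period) * 3) + 16L
  noise <- matrix(0, n_foci, n_max)
  if (config$noise_sd > 0)
    for (k in seq_len(n_foci))
      noise[k, ] <- generate_fractal_noise(n_max, config$noise_alpha,
                                           config$noise_sd)
  if (config$common_mode_sd > 0) {
    cm <- generate_fractal_noise(n_max, config$noise_alpha,
                                 config$common_mode_sd)
    noise <- sweep(noise, 2, cm, "+")
  }
  events <- if (!is.null(config$stretch_protocol))
    protocol_events(config$stretch_protocol) else NULL
  gains <- if (!is.null(config$stretch_protocol))
    list(stretch = config$stretch_protocol$rate_gain_stretch,
         release = config$stretch_protocol$rate_gain_release)
  decay_tau <- if (!is.null(config$stretch_protocol))
    config$stretch_protocol$decay_tau else 1

  G <- gain_integral_fn(events, gains, decay_tau)
  gmax <- if (is.null(gains)) 1 else max(1, unlist(gains))
  gmin <- if (is.null(gains)) 1 else min(1, unlist(gains))
  fire_times <- numeric(0)
  firing_focus <- integer(0)
  t_now <- 0
  cycle <- 1L
  while (cycle <= n_max) {
    # all clocks see the same g(t), so the smallest intrinsic period wins
    periods <- config$base_period[active] * exp(noise[active, cycle])
    k <- which.min(periods)
    P <- periods[k]
    if (is.null(events)) {
      t_fire <- t_now + P
    } else {
      G0 <- G(t_now)
      t_fire <- stats::uniroot(function(T) G(t_now + T) - G0 - P,
                               lower = P / gmax, upper = P / gmin,
                               extendInt = "upX", tol = 1e-10)$root + t_now
    }
    if (t_fire > config$duration) break
    fire_times <- c(fire_times, t_fire)
    firing_focus <- c(firing_focus, active[k])
    t_now <- t_fire
    cycle <- cycle + 1L
  }
  if (!length(fire_times))
    stop("duration too short to contain one beat")

  # propagation: focus -> electrode delay + jitter
  ex <- config$layout$x_cm
  ey <- config$layout$y_cm
  n_beats <- length(fire_times)
  n_el <- nrow(config$layout)
  delays <- matrix(0, n_foci, n_el)
  for (k in seq_len(n_foci))
    delays[k, ] <- sqrt((ex - config$focus_positions[k, 1])^2 +
                        (ey - config$focus_positions[k, 2])^2) /
      config$conduction_velocity
  act <- matrix(fire_times, n_beats, n_el) + delays[firing_focus, , drop = FALSE]
  if (config$jitter_sd > 0)
    act <- act + matrix(stats::rnorm(n_beats * n_el, 0, config$jitter_sd),
                        n_beats, n_el)
  colnames(act) <- as.character(config$layout$electrode)
  beat_times <- rowMeans(act)
  if (any(diff(beat_times) <= 0))
    stop("simulated mean beat times are not strictly increasing; ",
         "reduce jitter_sd or increase base_period")
  structure(list(beat_times = beat_times, firing_focus = firing_focus,
                 fire_times = fire_times, true_activation_times = act,
                 event_times = events,
                 noise_series = noise[, seq_len(n_beats), drop = FALSE],
                 config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d beats over %.1f s, %d foci (%d active in play)\n",
              length(x$beat_times), x$config$duration, x$config$n_foci,
              length(unique(x$firing_focus))))
  invisible(x)
}

#' Synthesize electrograms from ground truth
#'
#' Renders the multichannel sampled recording implied by a
#' [simulate_beats()] ground truth: one biphasic template per activation,
#' centred so its steepest downstroke falls on the sample nearest the true
#' activation time, plus additive white noise and slow sinusoidal baseline
#' drift. The event channel holds unit rectangular pulses spanning each
#' motor movement.
#'
#' @param truth a `"ground_truth"` object.
#' @param config the [sim_config()] used (defaults to `truth$config`).
#' @return an [mea_recording()].
#' @export
synthesize_electrograms <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  rate <- config$sampling_rate
  n_samp <- round(config$duration * rate)
  tpl <- waveform_template(config$waveform, rate)
  w <- tpl$values
  lw <- length(w)
  if (length(truth$beat_times) > 1 &&
      lw / rate > min(diff(truth$beat_times)))
    warning("waveform template wider than the minimum interbeat interval; ",
            "electrograms will overlap")
  n_el <- nrow(config$layout)
  sig <- matrix(0, n_el, n_samp)
  for (j in seq_len(n_el)) {
    ch <- numeric(n_samp)
    centers <- round(truth$true_activation_times[, j] * rate) + 1L
    for (c0 in centers) {
      i0 <- c0 - (tpl$center - 1L)
      i1 <- i0 + lw - 1L
      a <- max(1L, i0); b <- min(n_samp, i1)
      if (a <= b) ch[a:b] <- ch[a:b] + w[(a - i0 + 1L):(b - i0 + 1L)]
    }
    if (config$noise_floor_sd > 0)
      ch <- ch + stats::rnorm(n_samp, 0, config$noise_floor_sd)
    drift_a <- config$baseline_drift[["amplitude"]]
    if (drift_a > 0) {
      tt <- (seq_len(n_samp) - 1) / rate
      ch <- ch + drift_a * sin(2 * pi * tt / config$baseline_drift[["period_s"]] +
                               2 * pi * j / n_el)
    }
    sig[j, ] <- ch
  }
  if (config$quantize_12bit) {
    rng <- max(abs(sig))
    if (rng > 0) sig <- round(sig / rng * 2047) * (rng / 2047)
  }
  rownames(sig) <- as.character(config$layout$electrode)
  ev <- NULL
  if (!is.null(truth$event_times) && nrow(truth$event_times)) {
    ev <- numeric(n_samp)
    for (i in seq_len(nrow(truth$event_times))) {
      a <- max(1L, round(truth$event_times$motor_start[i] * rate) + 1L)
      b <- min(n_samp, round(truth$event_times$motor_end[i] * rate) + 1L)
      if (a <= b) ev[a:b] <- 1
    }
  }
  mea_recording(sig, rate, config$layout, event_channel = ev,
                meta = list(synthetic = TRUE))
}

#' Write ground truth to a JSON sidecar
#'
#' @param truth a `"ground_truth"` object.
#' @param path output JSON path.
#' @export
write_ground_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- list(beat_times = truth$beat_times,
              firing_focus = truth$firing_focus,
              fire_times = truth$fire_times,
              true_activation_times = truth$true_activation_times,
              event_times = truth$event_times)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
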