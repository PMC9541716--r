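#' Parse motor start/stop pulses from an event channel
#'
#' The stretch controller emits an electric pulse spanning every operation
#' of the linear motor stages; the pulse trace is digitized alongside the
#' electrograms. Edges are thresholded at half the channel's maximum and
#' consecutive pulses are labelled stretch/release alternately, starting
#' with stretch (the protocol always begins with a stretch).
#'
#' @param event_channel numeric pulse trace (may be empty/NULL).
#' @param rate sampling rate in Hz.
#' @return data frame `kind`, `motor_start`, `motor_end` (s); zero rows for
#'   an empty or flat channel.
#' @export
parse_motor_events <- function(event_channel, rate) {
  empty <- data.frame(kind = character(0), motor_start = numeric(0),
                      motor_end = numeric(0), stringsAsFactors = FALSE)
  if (is.null(event_channel) || !length(event_channel)) return(empty)
  mx <- max(event_channel)
  if (mx <= 0) return(empty)
  on <- event_channel > mx / 2
  d <- diff(on)
  rises <- which(d == 1) + 1L
  falls <- which(d == -1)
  if (on[1]) rises <- c(1L, rises)
  if (on[length(on) + 1L - 1L]) falls <- c(falls, length(event_channel))
  if (length(rises) != length(falls) || any(falls < rises))
    stop("protocol parse error: unpaired pulse edges in event channel")
  n <- length(rises)
  data.frame(kind = rep_len(c("stretch", "release"), n),
             motor_start = (rises - 1L) / rate,
             motor_end = (falls - 1L) / rate,
             stringsAsFactors = FALSE)
}

#' Epoch-average the beat-rate response to stretch or release
#'
#' Aligns the instantaneous-beat-rate series on the motor start of every
#' intervention of the requested kind, normalizes each repeat to its
#' baseline (the mean rate over the last 5 s before motor start) and
#' averages over repeats. The per-repeat peak is read from the bin ending
#' at the first bin edge at or past the motor end -- for a 2.0-s motor
#' phase and 0.5-s bins this is the bin covering 1.5-2.0 s (conventionally
#' plotted at 1.75 s), where the transient rate increase is maximal.
#' Partial or missing bins (e.g. long pauses) are treated as missing, not
#' zero, and are excluded from baselines and averages; repeats with an
#' empty or zero baseline are dropped with a warning.
#'
#' @param ibr an `"ibr_series"` (see [resample_ibr()]).
#' @param events motor event table from [parse_motor_events()] (columns
#'   `kind`, `motor_start`, `motor_end`).
#' @param kind `"stretch"` or `"release"`.
#' @param pre_s,post_s epoch window in s before/after motor start
#'   (defaults 10 and 30).
#' @param baseline_s baseline window length in s before motor start
#'   (default 5).
#' @return object of class `"epoch_average"`: `time_axis` (bin start times
#'   relative to motor start), `raw` and `normalized` (repeats x bins
#'   matrices), `mean_trace`, `baseline`, `peaks`, `mean_peak`,
#'   `peak_time` (bin centre, s), `kind`.
#' @export
epoch_average <- function(ibr, events, kind = c("stretch", "release"),
                          pre_s = 10, post_s = 30, baseline_s = 5) {
  stopifnot(inherits(ibr, "ibr_series"))
  kind <- match.arg(kind)
  ev <- events[events$kind == kind, , drop = FALSE]
  if (!nrow(ev)) stop("no '", kind, "' interventions in event table")
  dt <- ibr$dt
  pre_n <- round(pre_s / dt)
  post_n <- round(post_s / dt)
  n_bins <- pre_n + post_n
  time_axis <- (seq_len(n_bins) - pre_n - 1) * dt
  rate <- ifelse(ibr$partial, NA_real_, ibr$rate)
  raw <- matrix(NA_real_, nrow(ev), n_bins)
  for (r in seq_len(nrow(ev))) {
    k0 <- floor((ev$motor_start[r] - ibr$start_time) / dt) + 1L  # bin holding motor start
    idx <- (k0 - pre_n):(k0 + post_n - 1L)
    ok <- idx >= 1L & idx <= length(rate)
    raw[r, ok] <- rate[idx[ok]]
  }
  base_cols <- time_axis >= -baseline_s & time_axis < 0
  baseline <- rowMeans(raw[, base_cols, drop = FALSE], na.rm = TRUE)
  keep <- is.finite(baseline) & baseline > 0
  if (!all(keep))
    warning(sum(!keep), " repeat(s) excluded: no beats in baseline window")
  if (!any(keep)) stop("no repeat has a usable baseline")
  raw <- raw[keep, , drop = FALSE]
  ev <- ev[keep, , drop = FALSE]
  baseline <- baseline[keep]
  normalized <- raw / baseline
  mean_trace <- colMeans(normalized, na.rm = TRUE)
  mean_trace[!is.finite(mean_trace)] <- NA_real_
  dur <- ev$motor_end - ev$motor_start
  peak_rel <- ceiling(dur / dt - 1e-9)          # bin index after motor start
  peak_idx <- pre_n + peak_rel
  peaks <- normalized[cbind(seq_len(nrow(ev)), peak_idx)]
  structure(list(time_axis = time_axis, raw = raw, normalized = normalized,
                 mean_trace = mean_trace, baseline = baseline,
                 peaks = peaks, mean_peak = mean(peaks, na.rm = TRUE),
                 peak_time = (peak_rel[1] - 0.5) * dt, kind = kind,
                 dt = dt, n_repeats = nrow(ev)),
            class = "epoch_average")
}

#' @export
print.epoch_average <- function(x, ...) {
  cat(sprintf("<epoch_average> %s, %d repeats; mean peak fold-change %.2f at t = %.2f s\n",
              x$kind, x$n_repeats, x$mean_peak, x$peak_time))
  invisible(x)
}

#' Areal strain of the culture substrate
#'
#' Percentage change of in-plane area for in-plane strains `e_xx`, `e_yy`:
#' `100 * ((1 + e_xx) * (1 + e_yy) - 1)`. With the lateral constriction
#' compensated (e_yy = 0), 5% uniaxial strain increases the area by 5%;
#' 2% equibiaxial strain increases it by ~4%. Under incompressibility the
#' same percentage is the constriction along the normal axis.
#'
#' @param e_xx,e_yy strain fractions (> -1).
#' @return percentage area change.
#' @examples
#' areal_strain(0.05, 0)    # 5
#' areal_strain(0.02, 0.02) # 4.04
#' @export
areal_strain <- function(e_xx, e_yy) {
  if (any(c(e_xx, e_yy) <= -1)) stop("strains must be > -1")
  100 * ((1 + e_xx) * (1 + e_yy) - 1)
}

#' Summarize peak fold-changes across preparations
#'
#' Median and interquartile range of the per-preparation mean peak
#' fold-changes, plus a two-tailed test against the null fold-change
#' (1 = no effect): a Shapiro-Wilk gate selects the one-sample t test for
#' normally distributed values and the Wilcoxon signed rank test (normal
#' approximation, see [wilcoxon_signed_rank_p()]) otherwise.
#'
#' @param peaks per-preparation mean fold-changes (length >= 3).
#' @param null_value null fold-change (default 1).
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return list `n`, `median`, `iqr` (length-2), `test`, `p`,
#'   `shapiro_p`.
#' @export
summarize_across_preparations <- function(peaks, null_value = 1,
                                          alpha_normality = 0.05) {
  v <- as.numeric(peaks[is.finite(peaks)])
  if (length(v) < 3L) stop("need >= 3 preparations")
  if (stats::sd(v) == 0)  # all preparations identical: nothing to test
    return(list(n = length(v), median = stats::median(v),
                iqr = unname(stats::quantile(v, c(0.25, 0.75))),
                test = "none (degenerate)", p = NA_real_,
                shapiro_p = NA_real_))
  sw <- stats::shapiro.test(v)$p.value
  if (sw >= alpha_normality) {
    test <- "one-sample t"
    p <- one_sample_t_p(v, null_value)$p
  } else {
    test <- "Wilcoxon signed rank"
    p <- wilcoxon_signed_rank_p(v, null_value)$p
  }
  list(n = length(v), median = stats::median(v),
       iqr = unname(stats::quantile(v, c(0.25, 0.75))),
       test = test, p = p, shapiro_p = sw)
}
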