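#' Fit the slowness vector of one beat
#'
#' Ordinary least squares of activation time on electrode position,
#' `t_j = t_0 + s_x * x_j + s_y * y_j`. The coefficient vector
#' `s = (s_x, s_y)` is the conduction slowness (s/cm): the spatial gradient
#' of activation time, pointing in the propagation direction with magnitude
#' equal to the reciprocal of conduction speed. Slowness is preferred over
#' velocity as the primary fit because symmetric or near-simultaneous
#' activation gives a near-zero gradient, where velocity would diverge.
#'
#' @param times named numeric vector of activation times (s); names are
#'   electrode ids, NA entries are dropped.
#' @param layout layout data frame (`electrode`, `x_cm`, `y_cm`).
#' @return object of class `"slowness"`: `s_x`, `s_y` (s/cm), `t0` (s),
#'   `norm` (s/cm), `residual_rms` (s), `n_points`.
#' @export
fit_slowness <- function(times, layout) {
  layout <- validate_layout(layout)
  t <- times[!is.na(times)]
  if (is.null(names(t))) stop("'times' must be named by electrode id")
  if (length(t) < 4L)
    stop("slowness fit needs >= 4 electrodes (got ", length(t), ")")
  idx <- match(names(t), as.character(layout$electrode))
  if (anyNA(idx)) stop("unknown electrode id in 'times'")
  X <- cbind(1, layout$x_cm[idx], layout$y_cm[idx])
  if (qr(X)$rank < 3L)
    stop("electrode positions are collinear; slowness fit is rank deficient")
  fit <- stats::lm.fit(X, as.numeric(t))
  co <- fit$coefficients
  structure(list(s_x = unname(co[2]), s_y = unname(co[3]),
                 t0 = unname(co[1]),
                 norm = unname(sqrt(co[2]^2 + co[3]^2)),
                 residual_rms = sqrt(mean(fit$residuals^2)),
                 n_points = length(t)),
            class = "slowness")
}

#' @export
print.slowness <- function(x, ...) {
  cat(sprintf("<slowness> s = (%.4f, %.4f) s/cm, |s| = %.4f (n = %d, rms %.2e s)\n",
              x$s_x, x$s_y, x$norm, x$n_points, x$residual_rms))
  invisible(x)
}

#' Per-beat slowness table for a beat series
#'
#' Applies [fit_slowness()] to every spatially eligible beat; ineligible or
#' rank-deficient beats get NA coefficients and `eligible = FALSE`.
#'
#' @param bs a `"beat_series"` (see [cluster_beats()]).
#' @param layout electrode layout data frame.
#' @return data frame `beat`, `s_x`, `s_y`, `norm`, `residual_rms`,
#'   `n_points`, `eligible`.
#' @export
slowness_table <- function(bs, layout) {
  stopifnot(inherits(bs, "beat_series"))
  n <- nrow(bs$beats)
  out <- data.frame(beat = bs$beats$beat, s_x = NA_real_, s_y = NA_real_,
                    norm = NA_real_, residual_rms = NA_real_,
                    n_points = bs$beats$n_electrodes,
                    eligible = bs$beats$eligible)
  for (i in seq_len(n)) {
    if (!out$eligible[i]) next
    s <- tryCatch(fit_slowness(bs$times[i, ], layout), error = function(e) NULL)
    if (is.null(s)) { out$eligible[i] <- FALSE; next }
    out$s_x[i] <- s$s_x; out$s_y[i] <- s$s_y; out$norm[i] <- s$norm
    out$residual_rms[i] <- s$residual_rms
  }
  out
}

#' Convert slowness to conduction velocity
#'
#' `v = s / ||s||^2`: same direction as the slowness vector, reciprocal
#' magnitude. A zero slowness (symmetric activation) has no defined
#' velocity and raises an error rather than returning infinity.
#'
#' @param s a `"slowness"` object or numeric `c(s_x, s_y)` in s/cm.
#' @return list `v_x`, `v_y`, `speed` (cm/s).
#' @examples
#' slowness_to_velocity(c(0.0341, 0))$speed # 29.3 cm/s
#' @export
slowness_to_velocity <- function(s) {
  if (inherits(s, "slowness")) s <- c(s$s_x, s$s_y)
  s <- as.numeric(s)
  if (length(s) != 2L) stop("'s' must be a 2-vector")
  nrm2 <- sum(s^2)
  if (nrm2 == 0)
    stop("velocity undefined for zero slowness (symmetric activation)")
  v <- s / nrm2
  list(v_x = v[1], v_y = v[2], speed = 1 / sqrt(nrm2))
}

#' PCA of offset activation times
#'
#' Activation times of each beat are offset by the beat's mean
#' (`t'_ij = t_ij - m_i`) and principal components are computed over the
#' beats x electrodes matrix of `t'` (beats with missing electrodes are
#' excluded, since PCA needs a complete matrix). In monolayers driven by
#' peripheral wavefronts the first two components capture nearly all the
#' variance, consistent with the two-dimensionality of the preparation.
#'
#' @param bs a `"beat_series"`, or a complete beats x electrodes matrix of
#'   activation times.
#' @return object of class `"activation_pca"`: `loadings` (electrodes x
#'   components), `variance_fractions`, `cumulative_two`, `scores`,
#'   `n_beats`.
#' @export
pca_activation <- function(bs) {
  tm <- if (inherits(bs, "beat_series")) bs$times else as.matrix(bs)
  complete <- stats::complete.cases(tm)
  tm <- tm[complete, , drop = FALSE]
  if (nrow(tm) < 3L)
    stop("PCA needs >= 3 beats with complete electrode sets")
  tp <- tm - rowMeans(tm)
  p <- stats::prcomp(tp, center = TRUE, scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(list(loadings = p$rotation, variance_fractions = vf,
                 cumulative_two = sum(vf[1:min(2, length(vf))]),
                 scores = p$x, n_beats = nrow(tm)),
            class = "activation_pca")
}

#' @export
print.activation_pca <- function(x, ...) {
  cat(sprintf("<activation_pca> %d beats; first two components: %.1f%% of variance\n",
              x$n_beats, 100 * x$cumulative_two))
  invisible(x)
}

#' Shannon entropy of the slowness distribution
#'
#' The tips of the slowness vectors are histogrammed on a square grid of
#' `bin_size` x `bin_size` cells (anchored at the origin, half-open bins)
#' and the entropy `E = -sum p_i log(p_i)` of the occupied-bin fractions is
#' returned in nats. Spread-out distributions (frequent focus switching)
#' have high E; localized ones (a single stable focus) have low E.
#'
#' @param s_x,s_y slowness components (s/cm); alternatively `s_x` may be a
#'   data frame with columns `s_x`, `s_y` (NA rows dropped).
#' @param bin_size bin edge length in s/cm (default 0.005).
#' @return object of class `"slowness_entropy"`: `E` (nats),
#'   `occupied_bins`, `n`, `bin_size`.
#' @export
slowness_entropy <- function(s_x, s_y = NULL, bin_size = 0.005) {
  if (is.data.frame(s_x)) { s_y <- s_x$s_y; s_x <- s_x$s_x }
  keep <- !is.na(s_x) & !is.na(s_y)
  s_x <- s_x[keep]; s_y <- s_y[keep]
  if (!length(s_x)) stop("no slowness vectors")
  ix <- floor(s_x / bin_size)
  iy <- floor(s_y / bin_size)
  counts <- table(paste(ix, iy))
  p <- as.numeric(counts) / sum(counts)
  structure(list(E = -sum(p * log(p)), occupied_bins = length(p),
                 n = length(s_x), bin_size = bin_size),
            class = "slowness_entropy")
}

#' @export
print.slowness_entropy <- function(x, ...) {
  cat(sprintf("<slowness_entropy> E = %.3f nats over %d occupied bins (n = %d)\n",
              x$E, x$occupied_bins, x$n))
  invisible(x)
}

#' Interbeat slowness differences
#'
#' `d_i = ||s_{i+1} - s_i||`, the norm of the change in slowness between
#' consecutive beats, aligned with the IBI ending at beat i+1. Pairs
#' involving an ineligible beat yield NA. Large values mark beats where the
#' pacemaker focus moved.
#'
#' @param tab per-beat slowness table from [slowness_table()].
#' @return numeric vector of length `nrow(tab) - 1` (s/cm, NA for dropped
#'   pairs).
#' @export
interbeat_slowness_diff <- function(tab) {
  n <- nrow(tab)
  if (n < 2L) stop("need >= 2 beats")
  d <- sqrt(diff(tab$s_x)^2 + diff(tab$s_y)^2)
  d[!(tab$eligible[-n] & tab$eligible[-1])] <- NA_real_
  d
}
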