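#' Spearman correlation with a quantile density map
#'
#' Rank (quantile) correlation between two series, as used for the
#' IBI-versus-interbeat-slowness-difference relationship: Spearman's rho
#' (Pearson correlation of mid-ranks) plus a quantile-quantile density map.
#' Each observation is assigned to a 0.2 x 0.2 quantile rectangle (by
#' rank/n, boundary points going to the lower rectangle) and the relative
#' density of every rectangle is the observed count divided by the count
#' expected under independence (`n * 0.04`). Excess density in the
#' bottom-left and top-right corners is the signature of a positive
#' association.
#'
#' @param x,y numeric series of equal length >= 10 (pairs with NA in either
#'   are dropped).
#' @param n_bins quantile bins per axis (default 5).
#' @return object of class `"quantile_correlation"`: `rho`, `n`,
#'   `density_map` (`n_bins` x `n_bins`, x-quantile rows, mean 1).
#' @export
spearman_quantile_correlation <- function(x, y, n_bins = 5) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 10L) stop("need >= 10 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series")
  rho <- stats::cor(x, y, method = "spearman")
  qx <- rank(x, ties.method = "average") / n
  qy <- rank(y, ties.method = "average") / n
  bx <- pmax(1L, ceiling(qx * n_bins - 1e-9))
  by <- pmax(1L, ceiling(qy * n_bins - 1e-9))
  counts <- table(factor(bx, levels = seq_len(n_bins)),
                  factor(by, levels = seq_len(n_bins)))
  density <- unclass(counts) / (n / n_bins^2)
  structure(list(rho = rho, n = n, density_map = density),
            class = "quantile_correlation")
}

#' @export
print.quantile_correlation <- function(x, ...) {
  cat(sprintf("<quantile_correlation> rho = %.3f (n = %d)\n", x$rho, x$n))
  invisible(x)
}

#' Wilcoxon signed rank test, normal approximation
#'
#' Two-tailed signed rank test of `values` against `null_value`. Exact ties
#' with the null are dropped; ties among absolute differences get
#' mid-ranks. The p-value comes from the normal approximation
#' `z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)` without continuity
#' correction, which is the variant whose p-values this analysis reports
#' (e.g. n = 25 all-positive differences gives W = 325, z = 4.372,
#' p = 1.23e-5).
#'
#' @param values numeric series.
#' @param null_value hypothesized location (default 0).
#' @return list `method`, `n` (after dropping ties), `statistic` (W+, sum
#'   of positive ranks), `z`, `p`.
#' @export
wilcoxon_signed_rank_p <- function(values, null_value = 0) {
  d <- as.numeric(values) - null_value
  d <- d[d != 0]
  n <- length(d)
  if (n < 5L) stop("need >= 5 non-tied values")
  r <- rank(abs(d), ties.method = "average")
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  sg <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  z <- (W - mu) / sg
  list(method = "Wilcoxon signed rank (normal approximation)",
       n = n, statistic = W, z = z,
       p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' One-sample Student's t test (two-tailed)
#'
#' @param values numeric series (n >= 3, nonzero variance).
#' @param null_value hypothesized mean.
#' @return list `method`, `n`, `statistic` (t), `df`, `p`.
#' @export
one_sample_t_p <- function(values, null_value = 0) {
  v <- as.numeric(values)
  if (length(v) < 3L) stop("need >= 3 values")
  if (stats::sd(v) == 0) stop("zero variance: t test degenerate")
  ht <- stats::t.test(v, mu = null_value)
  list(method = "one-sample t", n = length(v),
       statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Normality-gated paired comparison
#'
#' Shapiro-Wilk test on the paired differences selects the test: paired
#' Student's t when the differences look normal (p >= `alpha_normality`),
#' Wilcoxon signed rank (normal approximation) otherwise. Two-tailed.
#'
#' @param before,after numeric series of equal length >= 3.
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return list `test`, `p`, `shapiro_p`, `n`.
#' @export
paired_or_wilcoxon <- function(before, after, alpha_normality = 0.05) {
  if (length(before) != length(after)) stop("series must have equal length")
  d <- as.numeric(after) - as.numeric(before)
  if (length(d) < 3L) stop("need >= 3 pairs")
  if (stats::sd(d) == 0) stop("zero-variance differences: test degenerate")
  sw <- stats::shapiro.test(d)$p.value
  if (sw >= alpha_normality) {
    list(test = "paired t", p = stats::t.test(d, mu = 0)$p.value,
         shapiro_p = sw, n = length(d))
  } else {
    list(test = "Wilcoxon signed rank",
         p = wilcoxon_signed_rank_p(d, 0)$p, shapiro_p = sw, n = length(d))
  }
}
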