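# Independent oracles used across the suite. These are deliberately naive
# (explicit loops, enumeration) and share no code with the package.

# Brute-force DFA fluctuation: non-overlapping left-anchored segments,
# per-segment cumulative sum, explicit 2-parameter least squares, then
# either the pooled RMS over all residuals or the mean per-segment RMS.
brute_df <- function(x, n, method = "pooled") {
  n_seg <- length(x) %/% n
  rms <- numeric(n_seg)
  ssq <- 0
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * n + 1):(s * n)]
    prof <- numeric(n)
    acc <- 0
    for (i in seq_len(n)) { acc <- acc + seg[i]; prof[i] <- acc }
    k <- seq_len(n)
    kbar <- mean(k); pbar <- mean(prof)
    slope <- sum((k - kbar) * (prof - pbar)) / sum((k - kbar)^2)
    inter <- pbar - slope * kbar
    res <- prof - (inter + slope * k)
    rms[s] <- sqrt(mean(res^2))
    ssq <- ssq + sum(res^2)
  }
  if (method == "pooled") sqrt(ssq / (n * n_seg)) else mean(rms)
}

# Exact two-tailed signed-rank p by enumeration of all sign assignments,
# mid-p convention (half weight on |W - mu| equal to the observed
# deviation), which is the quantity a normal approximation without
# continuity correction estimates.
exact_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  dev_obs <- abs(W_obs - mu)
  hits <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    dev <- abs(sum(r[signs]) - mu)
    if (dev > dev_obs + 1e-12) hits <- hits + 1
    else if (abs(dev - dev_obs) <= 1e-12) hits <- hits + 0.5
  }
  hits / 2^n
}

# Closed-form normal-equations plane fit t ~ 1 + x + y.
normal_eq_slowness <- function(t, x, y) {
  X <- cbind(1, x, y)
  beta <- solve(t(X) %*% X, t(X) %*% t)
  c(t0 = beta[1], s_x = beta[2], s_y = beta[3])
}

# Small noiseless simulator world reused by round-trip tests.
clean_sim <- function(duration = 20, n_foci = 2, seed = 1, ...) {
  sim_config(n_foci = n_foci, noise_sd = 0.05, jitter_sd = 0,
             duration = duration, noise_floor_sd = 0,
             baseline_drift = c(amplitude = 0, period_s = 2),
             seed = seed, ...)
}

# cluster_beats silencing the expected duplicate-detection warning
quiet_cluster <- function(...) suppressWarnings(cluster_beats(...))
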