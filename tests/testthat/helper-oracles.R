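# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# exhaustive enumeration of all monotone, continuous, boundary-anchored
# warping paths (steps (1,0), (0,1), (1,1)); returns the minimal weighted
# cost and the aligned (per-ref-index mean) sequence of the best path
brute_force_dtw <- function(s, r, w = rep(1, max(length(s), length(r)))) {
  n <- length(s); m <- length(r)
  best <- list(cost = Inf, aligned = NULL)
  rec <- function(i, j, cost, sums, counts) {
    cost <- cost + w[abs(i - j) + 1] * (s[i] - r[j])^2
    if (cost >= best$cost) return()
    sums[j] <- sums[j] + s[i]
    counts[j] <- counts[j] + 1
    if (i == n && j == m) {
      best <<- list(cost = cost, aligned = sums / counts)
      return()
    }
    if (i < n) rec(i + 1, j, cost, sums, counts)
    if (j < m) rec(i, j + 1, cost, sums, counts)
    if (i < n && j < m) rec(i + 1, j + 1, cost, sums, counts)
  }
  rec(1, 1, 0, numeric(m), integer(m))
  best
}

# naive O(N^2) sample-entropy pair counts, double loop over template pairs
naive_sampen_counts <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  list(A = A, B = B)
}

# exact 1-D Wasserstein-1 via the quantile-function formulation: both
# empirical inverse CDFs are constant on intervals of width 1/(na*nb)
quantile_w1 <- function(a, b) {
  na <- length(a); nb <- length(b)
  k <- na * nb
  u <- (seq_len(k) - 0.5) / k
  qa <- sort(a)[ceiling(u * na)]
  qb <- sort(b)[ceiling(u * nb)]
  mean(abs(qa - qb))
}

# band power fraction from a plain periodogram (no Welch averaging)
periodogram_band_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- (0:(n - 1)) * fs / n
  keep <- f > 0 & f <= fs / 2
  sum(p[keep & f >= lo & f <= hi]) / sum(p[keep])
}

# smooth band-limited random test signal (integrated noise, detrended)
random_smooth_signal <- function(n, seed) {
  set.seed(seed)
  x <- cumsum(rnorm(n))
  x - seq(x[1], x[length(x)], length.out = n)
}

# normalized cycle object as produced by cycle_envelopes
make_cycle <- function(values, onset = 1) {
  v <- as.numeric(values)
  structure(list(values = (v - mean(v)) / sd(v), onset_sample = onset,
                 length_samples = length(v), env_fs = 200),
            class = "dus_cycle")
}
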