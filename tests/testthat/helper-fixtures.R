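# Shared fixtures and independent oracles used across the suite.

# two-tone test signal sampled at fs for dur seconds
two_tone <- function(f1 = 5, f2 = 40, fs = 250, n = 5000, a1 = 1, a2 = 1) {
  t <- seq_len(n) / fs
  a1 * sin(2 * pi * f1 * t) + a2 * sin(2 * pi * f2 * t)
}

# seeded white-noise epoch
noise_epoch <- function(nc = 3, n = 1000, fs = 250, seed = 1,
                        label = "unknown") {
  set.seed(seed)
  epoch(matrix(rnorm(nc * n), nrow = nc), fs = fs, label = label)
}

# fraction of a signal's spectral energy at folded frequencies in [lo, hi] Hz
band_energy_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L)) * fs / n
  sum(p[f >= lo & f <= hi]) / sum(p)
}

# naive O(N^2) real-cepstrum oracle: explicit DFT sums, no FFT
naive_real_cepstrum <- function(x, eps_rel = 1e-12) {
  n <- length(x)
  j <- 0:(n - 1)
  X <- vapply(j, function(k)
    sum(x * exp(-2i * pi * k * j / n)), complex(1))
  lm <- log(pmax(Mod(X), eps_rel * max(Mod(X))))
  vapply(j, function(t)
    Re(sum(lm * exp(2i * pi * t * j / n))) / n, numeric(1))
}

# two-pass population-variance loop oracle
naive_pop_var <- function(v) {
  mu <- 0
  for (x in v) mu <- mu + x
  mu <- mu / length(v)
  s <- 0
  for (x in v) s <- s + (x - mu)^2
  s / length(v)
}

# brute-force one-way ANOVA F via the explicit sum-of-squares partition
naive_anova_f <- function(v, g) {
  g <- as.character(g)
  grand <- mean(v)
  ssr <- 0; sse <- 0
  for (lv in unique(g)) {
    vi <- v[g == lv]
    ssr <- ssr + length(vi) * (mean(vi) - grand)^2
    sse <- sse + sum((vi - mean(vi))^2)
  }
  k <- length(unique(g)); n <- length(v)
  (ssr / (k - 1)) / (sse / (n - k))
}

# exhaustive local-maxima scan of a smoothed magnitude spectrum (mirrors
# the documented definition but built independently, straight loops)
naive_spectral_peaks <- function(x, fs, n_peaks, smooth = 5) {
  n <- length(x)
  mag <- Mod(stats::fft(x))
  half <- n %/% 2
  idx <- seq(2, half + if (n %% 2 == 0) 0 else 1)
  m <- mag[idx]
  if (smooth > 1) {
    w <- if (smooth %% 2 == 0) smooth + 1 else smooth
    h <- (w - 1) / 2
    sm <- numeric(length(m))
    for (i in seq_along(m)) {
      lo <- max(1, i - h); hi <- min(length(m), i + h)
      sm[i] <- mean(m[lo:hi])
    }
    m <- sm
  }
  pk <- integer(0)
  for (i in 2:(length(m) - 1))
    if (m[i] > m[i - 1] && m[i] >= m[i + 1] && m[i] > 1e-8 * max(m))
      pk <- c(pk, i)
  ord <- order(-m[pk], pk)
  keep <- sort(pk[ord[seq_len(min(n_peaks, length(pk)))]])
  (idx[keep] - 1) * fs / n
}
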