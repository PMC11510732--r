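# Empirical wavelet transform: data-driven spectral boundaries from local
# maxima of the magnitude spectrum, a Meyer-type adaptive filter bank, and
# sub-band decomposition.
#
# Filter construction follows the standard Littlewood-Paley form. With
# ascending boundaries phi_1 < ... < phi_{m-1} (Hz) and transition-width
# parameter gamma, the scaling function is 1 below (1-gamma) phi_1, rolls
# off as cos(pi/2 * beta(.)) across [(1-gamma) phi_1, (1+gamma) phi_1], and
# is 0 above; wavelet i rises as sin(pi/2 * beta(.)) across the transition
# at phi_i, is 1 on the passband, and falls as cos(pi/2 * beta(.)) across
# the transition at phi_{i+1}; the last wavelet stays 1 up to Nyquist.
# beta(x) = x^4 (35 - 84 x + 70 x^2 - 20 x^3) so that
# beta(x) + beta(1-x) = 1, which makes squared responses sum to one at
# every frequency (partition of unity) provided gamma obeys the no-overlap
# bound gamma < min_i (phi_{i+1} - phi_i) / (phi_{i+1} + phi_i).

meyer_beta <- function(x) {
  y <- numeric(length(x))
  y[x >= 1] <- 1
  mid <- x > 0 & x < 1
  xm <- x[mid]
  y[mid] <- xm^4 * (35 - 84 * xm + 70 * xm^2 - 20 * xm^3)
  y
}

# smooth ramp 0 -> 1 across [(1-gamma) phi, (1+gamma) phi]
ewt_ramp <- function(w, phi, gamma) {
  meyer_beta((w - (1 - gamma) * phi) / (2 * gamma * phi))
}

#' Locate the dominant local maxima of a magnitude spectrum
#'
#' Computes the FFT magnitude spectrum of `signal` on the open band
#' (0, fs/2), optionally smooths it with a short centred moving average to
#' suppress noise-induced micro-maxima, enumerates the local maxima, and
#' keeps the `n_peaks` largest by magnitude (ties broken toward the lower
#' frequency). Peaks are returned in ascending frequency order.
#'
#' @param signal Real numeric vector, length at least 4.
#' @param fs Sampling rate in Hz.
#' @param n_peaks Number of maxima to keep (at least 1). When fewer local
#'   maxima exist, all are returned with a warning.
#' @param smooth Moving-average width in bins (odd; 1 disables smoothing).
#' @return Object of class `spectrum_peaks`: list with `freqs` (Hz,
#'   ascending), `mags` (magnitudes at those maxima), `m` (count).
#' @export
#' @examples
#' t <- seq(0, 20, by = 1 / 250)[-1]
#' x <- sin(2 * pi * 5 * t) + sin(2 * pi * 40 * t)
#' detect_spectral_maxima(x, fs = 250, n_peaks = 2)
detect_spectral_maxima <- function(signal, fs, n_peaks = 5L, smooth = 5L) {
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n < 4L) stop("signal must have at least 4 samples", call. = FALSE)
  if (n_peaks < 1L) stop("n_peaks must be >= 1", call. = FALSE)
  if (all(signal == 0))
    stop("degenerate spectrum: signal is identically zero", call. = FALSE)
  mag <- Mod(stats::fft(signal))
  half <- n %/% 2L                         # bins 0 .. half
  # interior bins strictly inside (0, fs/2)
  idx <- seq.int(2L, half + if (n %% 2L == 0L) 0L else 1L) # exclude DC, Nyquist
  m <- mag[idx]
  if (smooth > 1L) {
    w <- as.integer(smooth)
    if (w %% 2L == 0L) w <- w + 1L
    h <- (w - 1L) %/% 2L
    cs <- cumsum(c(0, m))
    lo <- pmax(seq_along(m) - h, 1L)
    hi <- pmin(seq_along(m) + h, length(m))
    m <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  L <- length(m)
  if (L >= 3L) {
    left <- m[2:(L - 1L)] > m[1:(L - 2L)]
    right <- m[2:(L - 1L)] >= m[3:L]
    pk <- which(left & right) + 1L
    # discard numerical-noise maxima far below the spectral peak
    pk <- pk[m[pk] > 1e-8 * max(m)]
  } else pk <- integer(0)
  if (length(pk) == 0L) {
    pk <- which.max(m)
    warning("no interior local maxima; using the global spectral maximum")
  }
  ord <- order(-m[pk], pk)                 # magnitude desc, lower freq first
  if (length(pk) < n_peaks)
    warning(sprintf("only %d local maxima found (requested %d)",
                    length(pk), n_peaks))
  keep <- pk[ord[seq_len(min(n_peaks, length(pk)))]]
  keep <- sort(keep)
  freqs <- (idx[keep] - 1L) * fs / n
  structure(list(freqs = freqs, mags = m[keep], m = length(keep)),
            class = "spectrum_peaks")
}

#' @export
print.spectrum_peaks <- function(x, ...) {
  cat(sprintf("<spectrum_peaks> %d maxima at %s Hz\n", x$m,
              paste(signif(x$freqs, 4), collapse = ", ")))
  invisible(x)
}

#' Midpoint spectral boundaries between successive maxima
#'
#' Each boundary is the centre of two progressive local maxima,
#' `phi_i = (w_i + w_{i+1}) / 2`; a single maximum yields an empty set
#' (one low-pass mode).
#'
#' @param peaks A [detect_spectral_maxima()] result, or a numeric vector of
#'   ascending peak frequencies in Hz.
#' @return Numeric vector of boundary frequencies (class `ewt_boundaries`).
#' @export
#' @examples
#' compute_boundaries(c(5, 40, 60))
compute_boundaries <- function(peaks) {
  f <- if (inherits(peaks, "spectrum_peaks")) peaks$freqs else as.numeric(peaks)
  if (length(f) < 1L) stop("need at least one maximum", call. = FALSE)
  if (is.unsorted(f, strictly = TRUE))
    stop("peak frequencies must be strictly increasing", call. = FALSE)
  phis <- if (length(f) == 1L) numeric(0) else (f[-length(f)] + f[-1L]) / 2
  structure(phis, class = "ewt_boundaries")
}

# largest admissible transition width for a boundary set (no-overlap bound,
# with the Nyquist edge included so the top transition stays in band)
gamma_bound <- function(phis, fs) {
  fn <- fs / 2
  edges <- c(phis, fn)
  if (length(phis) == 0L) return(1)
  min((edges[-1L] - edges[-length(edges)]) /
      (edges[-1L] + edges[-length(edges)]))
}

#' Build the Meyer-type empirical wavelet filter bank
#'
#' Samples the scaling function and the empirical wavelets on the two-sided
#' FFT frequency grid of length `n_fft`. The responses are real, lie in
#' \[0, 1\], and their squares sum to one at every grid point.
#'
#' @param boundaries A [compute_boundaries()] result or numeric vector of
#'   boundary frequencies in Hz (may be empty: single all-pass band).
#' @param n_fft Transform length (signal length).
#' @param fs Sampling rate in Hz.
#' @param gamma Transition-width parameter in (0, 1), or `"auto"` for 0.9
#'   times the no-overlap bound. An explicit value violating the bound is
#'   an error.
#' @return Object of class `ewt_bank`: list with `responses` (matrix,
#'   n_fft rows, one column per band, low to high), `boundaries`, `gamma`,
#'   `fs`, `n_fft`, `freq_abs` (folded frequency of each grid point).
#' @export
build_filter_bank <- function(boundaries, n_fft, fs, gamma = "auto") {
  phis <- as.numeric(boundaries)
  n_fft <- as.integer(n_fft)
  if (n_fft < 4L) stop("n_fft must be at least 4", call. = FALSE)
  if (length(phis) && (is.unsorted(phis, strictly = TRUE) ||
                       any(phis <= 0) || any(phis >= fs / 2)))
    stop("boundaries must be strictly increasing within (0, fs/2)",
         call. = FALSE)
  bnd <- gamma_bound(phis, fs)
  if (identical(gamma, "auto")) {
    gamma <- 0.9 * min(bnd, 1)
    if (gamma <= 0) stop("cannot choose gamma automatically", call. = FALSE)
  } else {
    gamma <- as.numeric(gamma)
    if (gamma <= 0 || gamma >= 1)
      stop("gamma must lie in (0, 1)", call. = FALSE)
    if (length(phis) >= 2L) {
      pair_bound <- min((phis[-1L] - phis[-length(phis)]) /
                        (phis[-1L] + phis[-length(phis)]))
      if (gamma >= pair_bound)
        stop(sprintf(
          "gamma = %g violates the no-overlap bound %g for these boundaries",
          gamma, pair_bound), call. = FALSE)
    }
  }
  f <- (seq_len(n_fft) - 1L) * fs / n_fft
  w <- pmin(f, fs - f)                     # folded (absolute) frequency
  nb <- length(phis) + 1L
  R <- matrix(0, n_fft, nb)
  if (length(phis) == 0L) {
    R[, 1L] <- 1                           # single all-pass scaling band
  } else {
    up <- vapply(phis, function(p) ewt_ramp(w, p, gamma), numeric(n_fft))
    # scaling: cos roll-off across phi_1
    R[, 1L] <- cos(pi / 2 * up[, 1L])
    if (nb > 2L) {
      for (i in 2L:(nb - 1L)) {
        R[, i] <- sin(pi / 2 * up[, i - 1L]) * cos(pi / 2 * up[, i])
      }
    }
    # last wavelet: rises at the top boundary, stays 1 up to Nyquist
    R[, nb] <- sin(pi / 2 * up[, nb - 1L])
  }
  structure(list(responses = R, boundaries = phis, gamma = gamma,
                 fs = fs, n_fft = n_fft, freq_abs = w),
            class = "ewt_bank")
}

#' @export
print.ewt_bank <- function(x, ...) {
  cat(sprintf("<ewt_bank> %d bands, boundaries {%s} Hz, gamma = %.4g\n",
              ncol(x$responses), paste(signif(x$boundaries, 4), collapse = ", "),
              x$gamma))
  invisible(x)
}

#' Decompose a signal into empirical wavelet sub-band modes
#'
#' Multiplies the signal spectrum by each band's squared response and
#' inverts, so every mode is real and the modes sum exactly to the input
#' (the squared responses form a partition of unity). Modes are ordered
#' low to high frequency, the first being the scaling (approximation) band.
#'
#' @param signal Real vector whose length equals the bank's `n_fft`.
#' @param bank An [build_filter_bank()] object.
#' @return Object of class `ewt_modes`: list with `modes` (matrix, one
#'   column per band), `bank`, `boundaries`.
#' @export
ewt_decompose <- function(signal, bank) {
  stopifnot(inherits(bank, "ewt_bank"))
  signal <- as.numeric(signal)
  if (length(signal) != bank$n_fft)
    stop(sprintf("signal length %d does not match bank n_fft %d",
                 length(signal), bank$n_fft), call. = FALSE)
  X <- stats::fft(signal)
  R2 <- bank$responses^2
  n <- bank$n_fft
  modes <- Re(stats::mvfft(R2 * X, inverse = TRUE)) / n
  colnames(modes) <- c("approx", if (ncol(R2) > 1L)
    paste0("mode", seq_len(ncol(R2) - 1L)))
  structure(list(modes = modes, bank = bank, boundaries = bank$boundaries),
            class = "ewt_modes")
}

#' @export
print.ewt_modes <- function(x, ...) {
  cat(sprintf("<ewt_modes> %d modes x %d samples, boundaries {%s} Hz\n",
              ncol(x$modes), nrow(x$modes),
              paste(signif(x$boundaries, 4), collapse = ", ")))
  invisible(x)
}

#' @export
plot.ewt_modes <- function(x, ...) {
  nm <- ncol(x$modes)
  op <- graphics::par(mfrow = c(nm, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(nm)) {
    graphics::plot(x$modes[, i], type = "l", ylab = colnames(x$modes)[i],
                   xlab = "", ...)
  }
  invisible(x)
}
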