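# Automated log-energy-based empirical wavelet reconstruction: score every
# sub-band mode by the natural log of its energy, select modes whose
# normalised score reaches a threshold, and sum the selected modes into a
# reconstructed signal.

#' Log energy of a sub-band mode
#'
#' Natural log of the sum of squared samples. Sums below 1e-300 are floored
#' before the log so an all-zero mode yields a finite (very negative) score
#' instead of -Inf.
#'
#' @param mode Real numeric vector.
#' @return Scalar log energy.
#' @export
#' @examples
#' log_energy(c(1, 1))  # log(2)
log_energy <- function(mode) {
  mode <- as.numeric(mode)
  if (!all(is.finite(mode))) stop("mode contains non-finite values", call. = FALSE)
  log(max(sum(mode^2), 1e-300))
}

#' Select sub-band modes by relative log energy
#'
#' Log energies are min-max normalised to \[0, 1\] (basis `"minmax"`, the
#' default); a mode is selected when its normalised score reaches
#' `threshold`. The highest-energy mode is always selected, and when all
#' scores are equal every mode is selected. Basis `"energy_share"` instead
#' scores each mode by its share of total (unlogged) energy, the alternative
#' reading of a relative-energy rule.
#'
#' @param energies Numeric vector of per-mode log energies (basis
#'   `"minmax"`) — or raw mode energies are recovered via `exp()` for
#'   `"energy_share"`.
#' @param threshold Selection threshold in (0, 1\]; default 0.10.
#' @param basis `"minmax"` or `"energy_share"`.
#' @return Object of class `mode_energy`: list with `log_energies`,
#'   `normalized`, `selected` (1-based indices), `threshold`, `basis`.
#' @export
#' @examples
#' select_modes(c(0, 5, 10), threshold = 0.10)
select_modes <- function(energies, threshold = 0.10,
                         basis = c("minmax", "energy_share")) {
  basis <- match.arg(basis)
  le <- as.numeric(energies)
  if (length(le) < 1L) stop("need at least one energy", call. = FALSE)
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  if (basis == "minmax") {
    rng <- max(le) - min(le)
    norm <- if (rng <= 0) rep(1, length(le)) else (le - min(le)) / rng
  } else {
    e <- exp(le)
    norm <- e / sum(e)
  }
  sel <- which(norm >= threshold)
  sel <- sort(unique(c(sel, which.max(le))))   # argmax always selected
  structure(list(log_energies = le, normalized = norm, selected = sel,
                 threshold = threshold, basis = basis),
            class = "mode_energy")
}

#' @export
print.mode_energy <- function(x, ...) {
  cat(sprintf("<mode_energy> %d modes, %d selected at threshold %.2g (%s)\n",
              length(x$log_energies), length(x$selected), x$threshold,
              x$basis))
  invisible(x)
}

#' Reconstruct a signal from selected modes
#'
#' Elementwise sum of the selected sub-band modes. With every mode selected
#' this reproduces the decomposed input (partition-of-unity property of the
#' bank).
#'
#' @param modes An [ewt_decompose()] result.
#' @param selected Non-empty integer vector of mode indices (1-based).
#' @return Numeric vector of the reconstructed signal.
#' @export
reconstruct_modes <- function(modes, selected) {
  stopifnot(inherits(modes, "ewt_modes"))
  selected <- as.integer(selected)
  if (length(selected) == 0L)
    stop("selection must be non-empty", call. = FALSE)
  if (any(selected < 1L | selected > ncol(modes$modes)))
    stop("selected mode indices out of range", call. = FALSE)
  rowSums(modes$modes[, selected, drop = FALSE])
}

# single-channel chain: maxima -> boundaries -> bank -> decompose ->
# log-energy selection -> reconstruction
aleewr_channel <- function(x, fs, n_peaks, gamma, threshold, basis, smooth) {
  if (all(x == 0)) {
    warning("all-zero channel passed through unchanged")
    return(list(signal = x, report = NULL))
  }
  pk <- suppressWarnings(detect_spectral_maxima(x, fs, n_peaks = n_peaks,
                                                smooth = smooth))
  bnd <- compute_boundaries(pk)
  bank <- build_filter_bank(bnd, n_fft = length(x), fs = fs, gamma = gamma)
  md <- ewt_decompose(x, bank)
  le <- apply(md$modes, 2L, log_energy)
  sel <- select_modes(le, threshold = threshold, basis = basis)
  list(signal = reconstruct_modes(md, sel$selected),
       report = list(n_modes = ncol(md$modes), boundaries = as.numeric(bnd),
                     log_energies = as.numeric(le),
                     normalized = sel$normalized, selected = sel$selected))
}

#' Adaptive wavelet reconstruction of an epoch (ALEEWR)
#'
#' Runs the full per-channel chain on a gain-normalised epoch: spectral
#' maxima detection, midpoint boundaries, Meyer-type filter bank, sub-band
#' decomposition, log-energy mode selection at `threshold`, and summation of
#' the selected modes. The output has the input's shape; a per-channel
#' selection report (mode count, boundaries, log energies, selected
#' indices) is attached as attribute `"aleewr_report"`.
#'
#' @param ep An [epoch()] or channels-by-samples matrix.
#' @param fs Sampling rate in Hz (taken from the epoch when omitted).
#' @param n_peaks Number of spectral maxima per channel (default 5).
#' @param gamma Filter-bank transition width, or `"auto"`.
#' @param threshold Log-energy selection threshold (default 0.10).
#' @param basis Normalisation basis for the threshold, see [select_modes()].
#' @param smooth Spectrum smoothing width in bins for peak detection.
#' @return Object of the input's type containing the reconstructed signal.
#' @export
aleewr_process <- function(ep, fs = NULL, n_peaks = 5L, gamma = "auto",
                           threshold = 0.10,
                           basis = c("minmax", "energy_share"),
                           smooth = 5L) {
  basis <- match.arg(basis)
  is_ep <- inherits(ep, "eeg_epoch") || inherits(ep, "eeg_recording")
  X <- if (is_ep) ep$data else as.matrix(ep)
  if (is.null(fs)) {
    if (!is_ep) stop("'fs' is required for matrix input", call. = FALSE)
    fs <- ep$fs
  }
  out <- X
  reports <- vector("list", nrow(X))
  for (ch in seq_len(nrow(X))) {
    res <- aleewr_channel(X[ch, ], fs, n_peaks, gamma, threshold, basis,
                          smooth)
    out[ch, ] <- res$signal
    reports[[ch]] <- res$report
  }
  names(reports) <- rownames(X)
  if (is_ep) {
    ep$data <- out
    attr(ep, "aleewr_report") <- reports
    ep
  } else {
    attr(out, "aleewr_report") <- reports
    out
  }
}
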