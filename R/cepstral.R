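# Real cepstrum and cepstral Hjorth descriptors. The cepstrum is the
# inverse FFT of the log-magnitude spectrum; activity, mobility and
# complexity are the classical Hjorth parameters evaluated on the cepstral
# coefficient sequence instead of the time series, quantifying the power,
# rate of change and irregularity of the quefrency-domain content.

#' Real cepstrum of a signal
#'
#' `c = Re(ifft(log(max(|fft(x)|, eps))))`. The magnitude floor `eps`
#' (relative to the peak spectral magnitude) keeps the log finite when the
#' spectrum has exact zeros; the imaginary residue of the inverse transform
#' is numerically zero for real input and is discarded.
#'
#' @param signal Real numeric vector, length at least 4, not identically
#'   zero.
#' @param eps_rel Magnitude floor relative to the spectral peak
#'   (default 1e-12).
#' @return Object of class `cepstrum`: numeric vector of cepstral
#'   coefficients (length of the input) with attribute `eps_floor`.
#' @export
#' @examples
#' real_cepstrum(c(1, 0.5, 0, 0))
real_cepstrum <- function(signal, eps_rel = 1e-12) {
  x <- as.numeric(signal)
  n <- length(x)
  if (n < 4L) stop("signal must have at least 4 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  if (all(x == 0))
    stop("degenerate input: signal is identically zero", call. = FALSE)
  mag <- Mod(stats::fft(x))
  floor_abs <- eps_rel * max(mag)
  cc <- Re(stats::fft(log(pmax(mag, floor_abs)), inverse = TRUE)) / n
  structure(cc, class = "cepstrum", eps_floor = floor_abs)
}

pop_var <- function(v) {
  mean((v - mean(v))^2)
}

#' Cepstral activity
#'
#' Population variance of the cepstral coefficients — the power of the
#' signal in the quefrency domain.
#'
#' @param c A [real_cepstrum()] result or numeric vector (length >= 2).
#' @return Non-negative scalar.
#' @export
cepstral_activity <- function(c) {
  v <- as.numeric(c)
  if (length(v) < 2L) stop("need at least 2 coefficients", call. = FALSE)
  pop_var(v)
}

#' Cepstral mobility
#'
#' Rate of change of the cepstrum: `sqrt(A(diff(c)) / A(c))` with `A` the
#' cepstral activity and the derivative taken as the unit-spacing first
#' difference. The literal no-radical ratio is available with
#' `sqrt = FALSE`.
#'
#' @param c A [real_cepstrum()] result or numeric vector (length >= 3).
#' @param sqrt Apply the square root (standard Hjorth convention,
#'   default TRUE).
#' @return Non-negative scalar.
#' @export
cepstral_mobility <- function(c, sqrt = TRUE) {
  v <- as.numeric(c)
  if (length(v) < 3L) stop("need at least 3 coefficients", call. = FALSE)
  a <- pop_var(v)
  if (a <= 0)
    stop("degenerate cepstrum: zero activity", call. = FALSE)
  r <- pop_var(diff(v)) / a
  if (sqrt) base::sqrt(r) else r
}

#' Cepstral complexity
#'
#' Irregularity of the cepstrum relative to a pure sinusoid:
#' `M(diff(c)) / M(c)` with `M` the cepstral mobility. A sampled sinusoid
#' has complexity close to 1; broadband irregular sequences score higher.
#'
#' @param c A [real_cepstrum()] result or numeric vector (length >= 4).
#' @param sqrt Passed through to [cepstral_mobility()].
#' @return Non-negative scalar.
#' @export
cepstral_complexity <- function(c, sqrt = TRUE) {
  v <- as.numeric(c)
  if (length(v) < 4L) stop("need at least 4 coefficients", call. = FALSE)
  m <- cepstral_mobility(v, sqrt = sqrt)
  if (m <= 0) stop("degenerate cepstrum: zero mobility", call. = FALSE)
  cepstral_mobility(diff(v), sqrt = sqrt) / m
}

#' Cepstral Hjorth feature vector of an epoch
#'
#' Computes the real cepstrum of every channel and its activity, mobility
#' and complexity, assembling a channel-major named vector
#' `(A<ch>, M<ch>, C<ch>)` per channel — 57 features for the 19-channel
#' 10-20 montage.
#'
#' @param ep An [epoch()] or channels-by-samples matrix (channel names from
#'   row names).
#' @param sqrt Mobility convention switch, see [cepstral_mobility()].
#' @return Named numeric vector of length `3 * n_channels`, with
#'   attributes `label` and `subject_id` when the input is an epoch.
#' @export
#' @examples
#' ep <- epoch(matrix(rnorm(2 * 500), nrow = 2), fs = 250)
#' names(extract_features(ep))
extract_features <- function(ep, sqrt = TRUE) {
  is_ep <- inherits(ep, "eeg_epoch")
  X <- if (is_ep) ep$data else as.matrix(ep)
  chn <- rownames(X)
  if (is.null(chn)) chn <- paste0("ch", seq_len(nrow(X)))
  vals <- numeric(3L * nrow(X))
  nms <- character(3L * nrow(X))
  for (i in seq_len(nrow(X))) {
    cc <- tryCatch(real_cepstrum(X[i, ]), error = function(e)
      stop(sprintf("channel %s: %s", chn[i], conditionMessage(e)),
           call. = FALSE))
    a <- cepstral_activity(cc)
    m <- tryCatch(cepstral_mobility(cc, sqrt = sqrt), error = function(e)
      stop(sprintf("channel %s (mobility): %s", chn[i], conditionMessage(e)),
           call. = FALSE))
    cx <- tryCatch(cepstral_complexity(cc, sqrt = sqrt), error = function(e)
      stop(sprintf("channel %s (complexity): %s", chn[i],
                   conditionMessage(e)), call. = FALSE))
    j <- 3L * (i - 1L)
    vals[j + 1:3] <- c(a, m, cx)
    nms[j + 1:3] <- paste0(c("A", "M", "C"), chn[i])
  }
  names(vals) <- nms
  if (is_ep) {
    attr(vals, "label") <- ep$label
    attr(vals, "subject_id") <- ep$subject_id
  }
  vals
}

#' Feature table for an epoch set
#'
#' One row per epoch with the named cepstral features plus `label` and
#' `subject_id` columns.
#'
#' @param eps An [epoch_set()].
#' @param sqrt Mobility convention switch.
#' @return A data frame.
#' @export
feature_table <- function(eps, sqrt = TRUE) {
  stopifnot(inherits(eps, "eeg_epochs"))
  rows <- lapply(eps$epochs, extract_features, sqrt = sqrt)
  X <- do.call(rbind, rows)
  df <- as.data.frame(X)
  df$label <- vapply(eps$epochs, function(e) e$label, character(1))
  df$subject_id <- vapply(eps$epochs, function(e) e$subject_id, character(1))
  df
}

#' Write a feature table as delimited text
#'
#' @param df A [feature_table()] data frame.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
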