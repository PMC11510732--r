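#' Standard 10-20 channel labels for a 19-electrode montage
#'
#' Ordered channel names of the classic 19-electrode 10-20 scalp layout,
#' the montage used throughout the synthetic generator defaults.
#'
#' @return Character vector of length 19.
#' @export
#' @examples
#' channels_1020()
channels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Construct a multichannel EEG recording
#'
#' A recording is a channels-by-samples numeric matrix together with its
#' sampling rate and ordered channel labels. All downstream stages
#' (artefact removal, segmentation, wavelet reconstruction) consume this
#' container.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Optional character vector of channel names; defaults
#'   to `"ch1"`, `"ch2"`, ... When 19 channels are supplied unnamed, the
#'   10-20 labels from [channels_1020()] are used.
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `channel_labels`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(200), nrow = 2), fs = 100)
#' rec
recording <- function(data, fs, channel_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L || ncol(data) < 2L)
    stop("recording needs >= 1 channel and >= 2 samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive finite scalar (Hz)", call. = FALSE)
  if (!all(is.finite(data)))
    stop("recording contains non-finite values", call. = FALSE)
  if (is.null(channel_labels)) {
    channel_labels <- if (nrow(data) == 19L) channels_1020()
                      else paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data))
    stop("length(channel_labels) must equal nrow(data)", call. = FALSE)
  rownames(data) <- channel_labels
  structure(list(data = data, fs = as.numeric(fs),
                 channel_labels = as.character(channel_labels)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Construct a single EEG epoch
#'
#' An epoch is one fixed-length window of a recording, carrying its class
#' label and the identifier of the subject it came from.
#'
#' @param data Channels-by-samples numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param label Class tag: `"healthy"`, `"schizophrenia"` or `"unknown"`.
#' @param subject_id Origin identifier (character).
#' @param channel_labels Optional channel names (see [recording()]).
#' @return An object of class `eeg_epoch`.
#' @export
epoch <- function(data, fs, label = "unknown", subject_id = "s0",
                  channel_labels = NULL) {
  label <- match.arg(label, c("healthy", "schizophrenia", "unknown"))
  rec <- recording(data, fs, channel_labels)
  structure(list(data = rec$data, fs = rec$fs,
                 channel_labels = rec$channel_labels,
                 label = label, subject_id = as.character(subject_id)),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d x %d @ %g Hz, label=%s, subject=%s\n",
              nrow(x$data), ncol(x$data), x$fs, x$label, x$subject_id))
  invisible(x)
}

#' Construct an epoch set
#'
#' @param epochs List of [epoch()] objects sharing sampling rate, channel
#'   count and window length.
#' @param provenance Free-form origin note (source file or generator seed).
#' @return An object of class `eeg_epochs`.
#' @export
epoch_set <- function(epochs, provenance = "") {
  if (length(epochs) == 0L)
    stop("epoch set must contain at least one epoch", call. = FALSE)
  fs <- vapply(epochs, function(e) e$fs, numeric(1))
  nc <- vapply(epochs, function(e) nrow(e$data), integer(1))
  ns <- vapply(epochs, function(e) ncol(e$data), integer(1))
  if (length(unique(fs)) != 1L || length(unique(nc)) != 1L ||
      length(unique(ns)) != 1L)
    stop("all epochs must share fs, channel count and window length",
         call. = FALSE)
  structure(list(epochs = epochs, provenance = as.character(provenance)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  e1 <- x$epochs[[1L]]
  labs <- table(vapply(x$epochs, function(e) e$label, character(1)))
  cat(sprintf("<eeg_epochs> %d epochs of %d x %d @ %g Hz\n",
              length(x$epochs), nrow(e1$data), ncol(e1$data), e1$fs))
  cat("  labels:", paste(sprintf("%s=%d", names(labs), labs), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
length.eeg_epochs <- function(x) length(x$epochs)

#' Read a multichannel EEG recording from disk
#'
#' Supports European Data Format (EDF) and delimited text. Delimited files
#' are laid out samples-per-row with a header line of channel names
#' (comma- or tab-separated) and require an explicit sampling rate because
#' the format carries none.
#'
#' @param path Path to the file.
#' @param fmt `"edf"`, `"delimited"`, or `"auto"` (by file extension).
#' @param fs_override Sampling rate in Hz; required for delimited input,
#'   overrides the header rate for EDF when given.
#' @return An [recording()] object with channels in file order.
#' @export
read_recording <- function(path, fmt = c("auto", "edf", "delimited"),
                           fs_override = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path))
    stop(sprintf("input file not found: '%s'", path), call. = FALSE)
  if (fmt == "auto") {
    fmt <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  if (fmt == "edf") {
    rec <- read_edf(path)
    if (!is.null(fs_override)) rec$fs <- as.numeric(fs_override)
    return(rec)
  }
  if (is.null(fs_override))
    stop("delimited input carries no sampling rate; supply 'fs_override'",
         call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "numeric", check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("delimited file contains non-numeric cells", call. = FALSE)
  if (!all(is.finite(m)))
    stop("delimited file contains non-finite values (NaN/Inf/NA)",
         call. = FALSE)
  recording(t(m), fs = fs_override, channel_labels = colnames(df))
}

#' Write a recording to disk
#'
#' Delimited output is samples-per-row with a header of channel names;
#' EDF output uses the minimal writer in [write_edf()].
#'
#' @param rec An [recording()] object.
#' @param path Output path.
#' @param fmt `"delimited"` or `"edf"`.
#' @param sep Field separator for delimited output.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, fmt = c("delimited", "edf"),
                            sep = ",") {
  stopifnot(inherits(rec, "eeg_recording"))
  fmt <- match.arg(fmt)
  if (fmt == "edf") return(write_edf(rec, path))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Segment a recording into fixed-length non-overlapping epochs
#'
#' Consecutive windows of `window_s` seconds are cut from the start of the
#' recording; a trailing partial window is dropped when `drop_partial` is
#' `TRUE` (the default). With `drop_partial = FALSE` a trailing partial
#' window is an error, so every returned epoch always has exactly
#' `round(window_s * fs)` samples.
#'
#' @param rec An [recording()] object.
#' @param window_s Window length in seconds (default 20).
#' @param drop_partial Drop (TRUE) or reject (FALSE) a trailing partial
#'   window.
#' @param label,subject_id Class tag and subject identifier stamped onto
#'   every produced epoch.
#' @return An [epoch_set()].
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(2 * 1000), nrow = 2), fs = 50)
#' segment(rec, window_s = 4)
segment <- function(rec, window_s = 20, drop_partial = TRUE,
                    label = "unknown", subject_id = "s0") {
  stopifnot(inherits(rec, "eeg_recording"))
  w <- as.integer(round(window_s * rec$fs))
  if (w < 2L)
    stop("window_s * fs must be at least 2 samples", call. = FALSE)
  n <- ncol(rec$data)
  k <- n %/% w
  if (k < 1L)
    stop(sprintf(
      "recording (%d samples) is shorter than one %g s window (%d samples)",
      n, window_s, w), call. = FALSE)
  if (!drop_partial && n %% w != 0L)
    stop("recording length is not an exact multiple of the window and drop_partial = FALSE",
         call. = FALSE)
  eps <- lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * w + 1L):(i * w)
    epoch(rec$data[, idx, drop = FALSE], rec$fs, label = label,
          subject_id = subject_id, channel_labels = rec$channel_labels)
  })
  epoch_set(eps, provenance = sprintf("segment(window_s=%g)", window_s))
}

#' Gain-normalise an epoch
#'
#' Removes per-channel gain and offset by z-scoring each channel to mean 0
#' and population standard deviation 1. Amplifier gain enters the cepstrum
#' only at quefrency zero, so this normalisation makes all downstream
#' cepstral descriptors gain-invariant.
#'
#' @param ep An [epoch()] (or any channels-by-samples matrix).
#' @return Object of the same type with every channel standardised.
#' @export
normalize_gain <- function(ep) {
  x <- if (inherits(ep, "eeg_epoch") || inherits(ep, "eeg_recording"))
    ep$data else as.matrix(ep)
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  sdp <- sqrt(rowSums(xc^2) / n)   # population SD
  bad <- which(sdp <= 0 | !is.finite(sdp))
  if (length(bad)) {
    nm <- rownames(x)
    nm <- if (is.null(nm)) as.character(bad) else nm[bad]
    stop(sprintf("degenerate (constant) channel(s): %s",
                 paste(nm, collapse = ", ")), call. = FALSE)
  }
  out <- xc / sdp
  if (inherits(ep, "eeg_epoch") || inherits(ep, "eeg_recording")) {
    ep$data <- out
    ep
  } else out
}
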