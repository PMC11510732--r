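# Minimal European Data Format (EDF) support.
#
# Implements the plain EDF container: one fixed 256-byte ASCII header, one
# 256-byte ASCII block per signal, then data records of 16-bit little-endian
# integers with linear physical/digital scaling. Enough to round-trip
# multichannel EEG written by this package and to ingest simple external
# EDF files; EDF+ annotations, discontinuous records and per-signal sampling
# rates that differ across channels are not supported.

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 1L, width = 0L)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

#' Write a recording as an EDF file
#'
#' Uses one-second data records, so the recording must have an integer
#' sampling rate and a whole number of seconds of data. Samples are
#' quantised to 16 bits over each channel's observed physical range, the
#' resolution the format itself imposes.
#'
#' @param rec An [recording()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  n <- ncol(rec$data)
  if (n %% fs != 0L)
    stop("EDF writer requires a whole number of seconds of data", call. = FALSE)
  nrec <- n %/% fs
  ns <- nrow(rec$data)

  pmin <- apply(rec$data, 1L, min)
  pmax <- apply(rec$data, 1L, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + ns), 8),
    edf_pad("", 44),
    edf_pad(nrec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig <- paste0(
    paste(edf_pad(rec$channel_labels, 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8L), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8L), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(sig, con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(rec$data[, idx, drop = FALSE])      # samples x channels
    dig <- round(sweep(sweep(block, 2L, pmin), 2L, scale, `*`)) + dmin
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Reads plain EDF with a common sampling rate across signals; channel
#' labels and order are preserved from the header.
#'
#' @param path Path to an EDF file.
#' @return An [recording()] object.
#' @seealso [write_edf()]
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readBin(con, "raw", n = width)
    trimws(rawToChar(raw))
  }
  ver <- rd(8)
  if (!identical(ver, "0"))
    stop(sprintf("not a plain EDF file (version field '%s')", ver),
         call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L)
    stop("EDF header: invalid signal count", call. = FALSE)

  rdv <- function(width, conv = identity) {
    vapply(seq_len(ns), function(i) conv(rd(width)), conv("0"))
  }
  labels <- rdv(16)
  rd(80 * ns)                      # transducer
  rd(8 * ns)                       # physical dimension
  pmin <- as.numeric(rdv(8))
  pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rd(80 * ns)                      # prefiltering
  spr <- as.integer(rdv(8))        # samples per record
  rd(32 * ns)
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a common sampling rate only", call. = FALSE)
  if (hdr_bytes != 256L * (1L + ns))
    warning("EDF header size field inconsistent; proceeding")

  fs <- spr[1L] / rec_dur
  dat <- matrix(0, nrow = ns, ncol = nrec * spr[1L])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1L], size = 2L, signed = TRUE,
                     endian = "little")
      idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
      dat[s, idx] <- (dig - dmin[s]) * scale[s] + pmin[s]
    }
  }
  recording(dat, fs = fs, channel_labels = labels)
}
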