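# Seeded two-class synthetic EEG generator. Each channel is the sum of a
# class-dependent resonant AR(2) oscillation, 1/f^slope background noise,
# and a shared blink artefact source projected onto the frontal channels
# with a fixed topography; per-channel random gains exercise gain
# normalisation. The generator records ground truth (blink source, times,
# topography, class parameters) so artefact-removal and classification
# stages can be validated without external data.

#' Synthetic dataset configuration
#'
#' Defaults emulate the geometry of a resting-state clinical EEG study:
#' 14 subjects per class, 19 channels of the 10-20 montage at 250 Hz, and
#' 36 twenty-second epochs per subject (504 epochs per class).
#'
#' The two classes differ in the resonant (alpha-band) process: healthy
#' channels oscillate around 10 Hz with a narrow bandwidth, while the
#' disease class shifts the resonance by `2 * class_effect` Hz, broadens
#' its bandwidth and adds a harmonic ripple to the spectral envelope —
#' differences a cepstral description is sensitive to. At
#' `class_effect = 0` the classes are exchangeable.
#'
#' @param n_subjects_per_class Subjects per class (default 14).
#' @param epochs_per_subject Twenty-second epochs per subject (default 36).
#' @param fs Sampling rate in Hz (default 250).
#' @param n_channels Channel count (default 19; 19 gets 10-20 labels).
#' @param class_effect Non-negative spectral separation control
#'   (default 1).
#' @param artifact_rate Blink rate in events per minute (default 4).
#' @param noise_slope 1/f exponent of the background noise (default 1).
#' @param seed Integer master seed.
#' @param window_s Epoch length in seconds (default 20).
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_subjects_per_class = 14L, epochs_per_subject = 36L,
                         fs = 250, n_channels = 19L, class_effect = 1.0,
                         artifact_rate = 4, noise_slope = 1.0, seed = 1L,
                         window_s = 20) {
  cfg <- list(n_subjects_per_class = as.integer(n_subjects_per_class),
              epochs_per_subject = as.integer(epochs_per_subject),
              fs = as.numeric(fs), n_channels = as.integer(n_channels),
              class_effect = as.numeric(class_effect),
              artifact_rate = as.numeric(artifact_rate),
              noise_slope = as.numeric(noise_slope),
              seed = as.integer(seed), window_s = as.numeric(window_s))
  with(cfg, {
    if (n_subjects_per_class < 1L || epochs_per_subject < 1L ||
        n_channels < 1L)
      stop("counts must be >= 1", call. = FALSE)
    if (fs <= 0) stop("fs must be positive", call. = FALSE)
    if (class_effect < 0) stop("class_effect must be >= 0", call. = FALSE)
    if (artifact_rate < 0) stop("artifact_rate must be >= 0", call. = FALSE)
  })
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d+%d subjects, %d x %gs epochs each, %d ch @ %g Hz\n",
    x$n_subjects_per_class, x$n_subjects_per_class, x$epochs_per_subject,
    x$window_s, x$n_channels, x$fs))
  cat(sprintf("  class_effect = %g, artifact_rate = %g/min, 1/f slope = %g, seed = %d\n",
              x$class_effect, x$artifact_rate, x$noise_slope, x$seed))
  invisible(x)
}

# class-dependent generative parameters of the resonant process
class_params <- function(class_label, class_effect) {
  ce <- class_effect
  if (class_label == "schizophrenia") {
    list(f0 = 10 + 2 * ce, radius = max(0.995 - 0.010 * ce, 0.90),
         harm_amp = 0.3 * ce)
  } else {
    list(f0 = 10, radius = 0.995, harm_amp = 0)
  }
}

ar2_resonance <- function(n, f0, radius, fs) {
  a <- c(2 * radius * cos(2 * pi * f0 / fs), -radius^2)
  x <- as.numeric(stats::filter(stats::rnorm(n), a, method = "recursive"))
  x / stats::sd(x)
}

# slow positive amplitude envelope (~1 s timescale): resting-state alpha
# waxes and wanes in bursts, which makes the channel processes
# super-Gaussian — the non-Gaussianity the ICA source model assumes
slow_envelope <- function(n) {
  e <- as.numeric(stats::filter(stats::rnorm(n), 0.996, method = "recursive"))
  e <- abs(e)
  e / mean(e)
}

pink_noise <- function(n, slope) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L))
  shape <- c(1, f[-1L]^(-slope / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

blink_topography <- function(channel_labels) {
  topo <- c(Fp1 = 1.0, Fp2 = 1.0, F7 = 0.6, F3 = 0.5, Fz = 0.45,
            F4 = 0.5, F8 = 0.6)
  out <- numeric(length(channel_labels))
  names(out) <- channel_labels
  hit <- intersect(names(topo), channel_labels)
  out[hit] <- topo[hit]
  out
}

#' Generate one synthetic subject recording with ground truth
#'
#' @param cfg A [synth_config()].
#' @param class_label `"healthy"` or `"schizophrenia"`.
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier stamped onto the recording.
#' @return List with `recording` (an [recording()]) and `truth` (blink
#'   source, blink centre samples, topography, per-channel gains, class
#'   parameters).
#' @export
generate_recording <- function(cfg, class_label = "healthy",
                               subject_seed = 1L, subject_id = "s1") {
  stopifnot(inherits(cfg, "synth_config"))
  class_label <- match.arg(class_label, c("healthy", "schizophrenia"))
  n <- as.integer(round(cfg$epochs_per_subject * cfg$window_s * cfg$fs))
  nc <- cfg$n_channels
  labels <- if (nc == 19L) channels_1020() else paste0("ch", seq_len(nc))
  pars <- class_params(class_label, cfg$class_effect)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(subject_seed))

  X <- matrix(0, nc, n)
  for (ch in seq_len(nc)) {
    brain <- ar2_resonance(n, pars$f0, pars$radius, cfg$fs)
    if (pars$harm_amp > 0)
      brain <- brain + pars$harm_amp *
        ar2_resonance(n, 2 * pars$f0, 0.99, cfg$fs)
    brain <- brain * slow_envelope(n)
    brain <- brain / stats::sd(brain)
    X[ch, ] <- brain + 0.7 * pink_noise(n, cfg$noise_slope)
  }

  # shared blink source: smooth ~0.4 s bumps at Poisson rate
  blink <- numeric(n)
  dur <- as.integer(round(0.4 * cfg$fs))
  n_blinks <- stats::rpois(1L, cfg$artifact_rate * n / cfg$fs / 60)
  centers <- integer(0)
  if (n_blinks > 0L) {
    centers <- sort(sample.int(n - dur, n_blinks)) + dur %/% 2L
    bump <- sin(pi * seq_len(dur) / (dur + 1L))^2
    for (cc in centers) {
      idx <- (cc - dur %/% 2L) + seq_len(dur) - 1L
      idx <- idx[idx >= 1L & idx <= n]
      blink[idx] <- blink[idx] + stats::runif(1L, 0.8, 1.2) *
        bump[seq_along(idx)]
    }
  }
  topo <- blink_topography(labels)
  X <- X + 8 * (topo %o% blink)

  gains <- stats::runif(nc, 0.5, 2)
  X <- X * gains

  rec <- recording(X, fs = cfg$fs, channel_labels = labels)
  list(recording = rec,
       truth = list(blink_source = blink, blink_centers = centers,
                    topography = topo, gains = gains, params = pars,
                    class_label = class_label, subject_id = subject_id,
                    subject_seed = as.integer(subject_seed)))
}

# deterministic per-subject seed derived from the master seed (kept below
# 2^31 - 1)
subject_seed_for <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * index) %% 2147483647)
}

#' Generate a balanced two-class synthetic dataset
#'
#' One recording per subject, `n_subjects_per_class` per class, with
#' per-subject seeds derived deterministically from the master seed.
#'
#' @param cfg A [synth_config()].
#' @return Object of class `synth_dataset`: list with `recordings` (each a
#'   [generate_recording()] result), `cfg`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  recs <- vector("list", 2L * cfg$n_subjects_per_class)
  i <- 0L
  for (cls in c("healthy", "schizophrenia")) {
    for (s in seq_len(cfg$n_subjects_per_class)) {
      i <- i + 1L
      recs[[i]] <- generate_recording(
        cfg, class_label = cls,
        subject_seed = subject_seed_for(cfg$seed, i),
        subject_id = sprintf("%s_%02d", substr(cls, 1L, 2L), s))
    }
  }
  structure(list(recordings = recs, cfg = cfg), class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cls <- vapply(x$recordings, function(r) r$truth$class_label, character(1))
  cat(sprintf("<synth_dataset> %d recordings (%s)\n", length(x$recordings),
              paste(sprintf("%s=%d", names(table(cls)), table(cls)),
                    collapse = ", ")))
  invisible(x)
}
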