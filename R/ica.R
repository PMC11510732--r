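# Fixed-point FastICA with the log-cosh contrast and symmetric
# decorrelation, plus a robust-kurtosis artefact-flagging rule and
# mixing-matrix reconstruction with selected components removed.

excess_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 <= 0) return(0)
  mean(x^4) / m2^2 - 3
}

# inverse symmetric square root of a positive-definite matrix
inv_sqrtm <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values <= 1e-12 * max(e$values)))
    stop("rank-deficient data: whitening failed", call. = FALSE)
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

#' Fit FastICA to a multichannel epoch or recording
#'
#' Models the observed channels `y` as a linear mixture `y = A z` of
#' statistically independent sources `z`, and estimates the unmixing map
#' `W` (so that `z = W y`) by the fixed-point FastICA algorithm: the data
#' are centred and whitened, then rotation rows are updated with the
#' log-cosh non-linearity under symmetric decorrelation until the largest
#' direction change falls below `tol`.
#'
#' @param x An [epoch()], [recording()] or channels-by-samples matrix.
#' @param n_components Number of components to extract (default: all
#'   channels). Must not exceed the channel count.
#' @param seed Integer seed for the random initial rotation; fixed seed
#'   gives bit-identical results.
#' @param tol Convergence tolerance on the fixed-point direction change.
#' @param max_iter Iteration cap; non-convergence yields a model with
#'   `converged = FALSE` and a warning.
#' @param est_every Temporal subsampling stride for the *estimation* of the
#'   whitener and rotation (default 1 = use every sample). The unmixing
#'   map is then applied to the full data; with tens of thousands of
#'   samples per channel a stride of 2-4 leaves the estimate essentially
#'   unchanged while cutting the fit cost proportionally.
#' @return An object of class `fastica` with elements `unmixing` (W, in
#'   original channel coordinates), `mixing` (its pseudo-inverse), `sources`
#'   (z, unit variance rows), `whitener`, `rotation` (orthonormal rows in
#'   whitened space), `center`, `seed`, `converged`, `n_iter`.
#' @export
#' @examples
#' set.seed(1)
#' s <- rbind(runif(2000, -1, 1), rexp(2000) * sample(c(-1, 1), 2000, TRUE))
#' x <- matrix(c(1, .5, .5, 1), 2) %*% s
#' m <- fit_fastica(x, seed = 7)
#' m
fit_fastica <- function(x, n_components = NULL, seed = 1L,
                        tol = 1e-6, max_iter = 500L, est_every = 1L) {
  X <- if (inherits(x, "eeg_epoch") || inherits(x, "eeg_recording"))
    x$data else as.matrix(x)
  if (!all(is.finite(X))) stop("input contains non-finite values", call. = FALSE)
  p <- nrow(X); n <- ncol(X)
  if (is.null(n_components)) n_components <- p
  k <- as.integer(n_components)
  if (k < 1L || k > p)
    stop("n_components must be between 1 and the channel count", call. = FALSE)

  ctr <- rowMeans(X)
  Xc <- X - ctr
  est_every <- max(1L, as.integer(est_every))
  Xe <- if (est_every > 1L)
    Xc[, seq.int(1L, n, by = est_every), drop = FALSE] else Xc
  ne <- ncol(Xe)
  C <- tcrossprod(Xe) / ne
  e <- eigen(C, symmetric = TRUE)
  if (any(e$values[seq_len(k)] <= 1e-12 * max(e$values)))
    stop("rank-deficient data: whitening failed", call. = FALSE)
  # whitener projects onto the k leading principal axes and rescales
  K <- diag(1 / sqrt(e$values[seq_len(k)]), k) %*% t(e$vectors[, seq_len(k), drop = FALSE])
  Z <- K %*% Xe                       # k x n, identity covariance

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  W <- matrix(stats::rnorm(k * k), k, k)
  W <- inv_sqrtm(tcrossprod(W)) %*% W   # orthonormal rows

  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    U <- W %*% Z
    G <- tanh(U)
    gprime <- 1 - G^2
    W_new <- tcrossprod(G, Z) / ne - diag(rowMeans(gprime), k) %*% W
    W_new <- inv_sqrtm(tcrossprod(W_new)) %*% W_new
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("FastICA did not converge in %d iterations (delta above tol)",
                    max_iter))

  unmix <- W %*% K                    # k x p, z = unmix %*% (x - center)
  # pseudo-inverse mixing: x ~ mixing %*% z + center
  mixing <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k) %*% t(W)
  sources <- unmix %*% Xc             # full-length sources
  structure(list(unmixing = unmix, mixing = mixing, sources = sources,
                 whitener = K, rotation = W, center = ctr,
                 seed = as.integer(seed), converged = converged,
                 n_iter = it,
                 channel_labels = if (inherits(x, "eeg_epoch") ||
                                      inherits(x, "eeg_recording"))
                   x$channel_labels else rownames(X),
                 input = x),
            class = "fastica")
}

#' @export
print.fastica <- function(x, ...) {
  cat(sprintf("<fastica> %d components from %d channels; %s in %d iterations\n",
              nrow(x$sources), length(x$center),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Flag artefact-like independent components
#'
#' Scores every source by excess kurtosis and flags those whose robust
#' z-score (median/MAD across components) exceeds `kurtosis_z` and whose
#' excess kurtosis also exceeds the absolute floor `min_kurtosis`.
#' Transient artefacts such as eye blinks concentrate energy in brief
#' bumps and are strongly super-Gaussian (excess kurtosis in the tens),
#' while ongoing cortical background activity is near-Gaussian; the
#' absolute floor keeps sampling noise in the kurtosis of genuinely
#' Gaussian components from ever tripping the outlier rule. Never flags
#' every component.
#'
#' @param model A [fit_fastica()] model with at least two sources.
#' @param kurtosis_z Robust z-score threshold (default 3).
#' @param min_kurtosis Absolute excess-kurtosis floor a flagged component
#'   must exceed (default 1).
#' @return Integer vector of flagged component indices (possibly empty),
#'   with per-component kurtosis attached as attribute `"kurtosis"`.
#' @export
flag_artifact_components <- function(model, kurtosis_z = 3.0,
                                     min_kurtosis = 1.0) {
  stopifnot(inherits(model, "fastica"))
  k <- nrow(model$sources)
  if (k < 2L) stop("need at least 2 components to flag outliers", call. = FALSE)
  ku <- apply(model$sources, 1L, excess_kurtosis)
  med <- stats::median(ku)
  s <- stats::mad(ku)
  if (s < 1e-8) s <- stats::sd(ku)
  if (!is.finite(s) || s < 1e-8) {
    flags <- integer(0)
  } else {
    z <- (ku - med) / s
    flags <- which(z > kurtosis_z & ku > min_kurtosis)
  }
  if (length(flags) == k)                      # never flag everything
    flags <- flags[-which.min(ku[flags])]
  attr(flags, "kurtosis") <- ku
  flags
}

#' Reconstruct the signal with selected components removed
#'
#' Zeroes the dropped sources, maps the remainder back through the mixing
#' matrix and restores channel means.
#'
#' @param model A [fit_fastica()] model.
#' @param drop Integer indices of components to remove (may be empty;
#'   dropping all components is an error).
#' @return Channels-by-samples matrix of the cleaned signal, or an object
#'   matching the input type when the model was fitted on an epoch or
#'   recording.
#' @export
remove_components <- function(model, drop = integer(0)) {
  stopifnot(inherits(model, "fastica"))
  k <- nrow(model$sources)
  drop <- as.integer(drop)
  if (any(drop < 1L | drop > k))
    stop("component indices out of range", call. = FALSE)
  if (length(unique(drop)) >= k)
    stop("cannot drop every component", call. = FALSE)
  S <- model$sources
  if (length(drop)) S[drop, ] <- 0
  clean <- model$mixing %*% S + model$center
  x <- model$input
  if (inherits(x, "eeg_epoch") || inherits(x, "eeg_recording")) {
    rownames(clean) <- x$channel_labels
    x$data <- clean
    x
  } else {
    if (!is.null(model$channel_labels)) rownames(clean) <- model$channel_labels
    clean
  }
}

#' One-call artefact cleanup
#'
#' Fits FastICA, flags kurtosis-outlier components and reconstructs the
#' signal without them.
#'
#' @inheritParams fit_fastica
#' @inheritParams flag_artifact_components
#' @param enabled Set `FALSE` to return the input untouched (cleanup off).
#' @return Cleaned object of the input's type, with the fitted model and
#'   flagged indices attached as attributes `"ica"` and `"flagged"`.
#' @export
clean_artifacts <- function(x, n_components = NULL, seed = 1L,
                            kurtosis_z = 3.0, tol = 1e-6, max_iter = 500L,
                            est_every = 1L, enabled = TRUE) {
  if (!enabled) return(x)
  m <- fit_fastica(x, n_components = n_components, seed = seed,
                   tol = tol, max_iter = max_iter, est_every = est_every)
  flags <- flag_artifact_components(m, kurtosis_z = kurtosis_z)
  out <- remove_components(m, flags)
  attr(out, "ica") <- m
  attr(out, "flagged") <- as.integer(flags)
  out
}
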