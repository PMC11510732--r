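# End-to-end orchestration: (synthesise or read) -> artefact cleanup ->
# segmentation -> gain normalisation -> adaptive wavelet reconstruction ->
# cepstral features -> ANOVA ranking -> KNN cross-validation. Recordings
# are processed one subject at a time so memory stays bounded by a single
# recording plus the accumulated feature table.

# small FNV-1a hash so every artifact can embed its config fingerprint
# without external dependencies
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  b <- utf8ToInt(s)
  h <- 2166136261
  for (x in b) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(x))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' Bundles and validates every stage's parameters. Validation happens here,
#' before any computation: an out-of-range `top_k` or threshold fails
#' immediately.
#'
#' @param synth A [synth_config()] describing the synthetic input; exactly
#'   one of `synth` and `paths` must be given.
#' @param paths Optional named list `list(files =, labels =, subject_ids =,
#'   fs_override =)` of recordings to read instead of synthesising.
#' @param window_s Epoch length in seconds (default 20; for synthetic input
#'   the generator's own window is used).
#' @param ica List: `enabled`, `kurtosis_z`, `seed`, `tol`, `max_iter`,
#'   `scope` (`"recording"` to clean each recording before segmentation,
#'   the default, or `"epoch"`).
#' @param ewt List: `n_peaks`, `gamma`, `smooth`.
#' @param aleewr List: `threshold`, `basis`.
#' @param selection List: `top_k`, `scope` (`"fold"` or `"global"`).
#' @param classifier List: `spec` (a [knn_spec()]), `folds`, `repeats`,
#'   `seed`, `subject_cv` (grouped, leakage-free folds when TRUE).
#' @param out_dir Optional directory for artifacts (feature table, ranked
#'   weights, CV report, run log).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, paths = NULL,
                            window_s = 20,
                            ica = list(), ewt = list(), aleewr = list(),
                            selection = list(), classifier = list(),
                            out_dir = NULL) {
  merge_def <- function(user, def) {
    bad <- setdiff(names(user), names(def))
    if (length(bad))
      stop(sprintf("unknown option(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    def[names(user)] <- user
    def
  }
  ica <- merge_def(ica, list(enabled = TRUE, kurtosis_z = 3.0, seed = 1L,
                             tol = 1e-6, max_iter = 500L, est_every = 3L,
                             scope = "recording"))
  ewt <- merge_def(ewt, list(n_peaks = 5L, gamma = "auto", smooth = 5L))
  aleewr <- merge_def(aleewr, list(threshold = 0.10, basis = "minmax"))
  selection <- merge_def(selection, list(top_k = 10L, scope = "fold"))
  classifier <- merge_def(classifier,
                          list(spec = knn_spec("fknn"), folds = 10L,
                               repeats = 20L, seed = 1L,
                               subject_cv = FALSE))
  if (!is.null(synth) && !inherits(synth, "synth_config"))
    stop("'synth' must be a synth_config()", call. = FALSE)
  if (is.null(synth) == is.null(paths))
    stop("exactly one of 'synth' or 'paths' is required", call. = FALSE)
  n_channels <- if (!is.null(synth)) synth$n_channels else NA_integer_
  if (!is.na(n_channels) && selection$top_k > 3L * n_channels)
    stop(sprintf("top_k = %d exceeds the %d features available",
                 selection$top_k, 3L * n_channels), call. = FALSE)
  if (aleewr$threshold <= 0 || aleewr$threshold > 1)
    stop("aleewr threshold must lie in (0, 1]", call. = FALSE)
  if (!ewt$n_peaks %in% 1:16)
    stop("ewt n_peaks must lie in 1..16", call. = FALSE)
  ica$scope <- match.arg(ica$scope, c("recording", "epoch"))
  selection$scope <- match.arg(selection$scope, c("fold", "global"))
  cfg <- structure(list(synth = synth, paths = paths, window_s = window_s,
                        ica = ica, ewt = ewt, aleewr = aleewr,
                        selection = selection, classifier = classifier,
                        out_dir = out_dir),
                   class = "pipeline_config")
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>", config_hash(unclass(x)), "\n")
  cat(sprintf("  input: %s\n",
              if (!is.null(x$synth)) "synthetic" else "files"))
  cat(sprintf("  ica: %s (kurtosis_z %.2g, scope %s)\n",
              if (x$ica$enabled) "on" else "off", x$ica$kurtosis_z,
              x$ica$scope))
  cat(sprintf("  ewt: n_peaks %d, gamma %s; aleewr: threshold %.2g (%s)\n",
              x$ewt$n_peaks, as.character(x$ewt$gamma),
              x$aleewr$threshold, x$aleewr$basis))
  cat(sprintf("  selection: top %d (%s); classifier: %s, %d-fold x %d\n",
              x$selection$top_k, x$selection$scope, x$classifier$spec$name,
              x$classifier$folds, x$classifier$repeats))
  invisible(x)
}

# clean -> segment -> normalise -> reconstruct -> features for one subject
process_recording <- function(rec, cfg, label, subject_id) {
  if (cfg$ica$enabled && cfg$ica$scope == "recording") {
    rec <- clean_artifacts(rec, seed = cfg$ica$seed,
                           kurtosis_z = cfg$ica$kurtosis_z,
                           tol = cfg$ica$tol, max_iter = cfg$ica$max_iter,
                           est_every = cfg$ica$est_every)
  }
  eps <- segment(rec, window_s = cfg$window_s, label = label,
                 subject_id = subject_id)
  rows <- lapply(eps$epochs, function(ep) {
    if (cfg$ica$enabled && cfg$ica$scope == "epoch")
      ep <- clean_artifacts(ep, seed = cfg$ica$seed,
                            kurtosis_z = cfg$ica$kurtosis_z,
                            tol = cfg$ica$tol, max_iter = cfg$ica$max_iter,
                            est_every = cfg$ica$est_every)
    ep <- normalize_gain(ep)
    ep <- aleewr_process(ep, n_peaks = cfg$ewt$n_peaks,
                         gamma = cfg$ewt$gamma,
                         threshold = cfg$aleewr$threshold,
                         basis = cfg$aleewr$basis, smooth = cfg$ewt$smooth)
    extract_features(ep)
  })
  X <- do.call(rbind, rows)
  df <- as.data.frame(X)
  df$label <- label
  df$subject_id <- subject_id
  df
}

#' Run the full screening pipeline
#'
#' Executes every stage in order and returns the feature table, the global
#' ANOVA ranking, and the cross-validation report as one classed result.
#' With an `out_dir` configured, writes the feature table, ranked weights,
#' a CV summary and a run log (all parameters, seeds and the config hash)
#' as delimited/plain text.
#'
#' @param cfg A [pipeline_config()].
#' @param progress Print a line per subject while processing.
#' @return Object of class `aleewr_pipeline` with elements `features`
#'   (data frame), `ranking` (global [rank_and_select()]), `cv`
#'   (a `cv_report`), `config`, `config_hash`.
#' @export
run_pipeline <- function(cfg = pipeline_config(synth = synth_config()),
                         progress = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  hash <- config_hash(unclass(cfg))
  tables <- list()
  if (!is.null(cfg$synth)) {
    sc <- cfg$synth
    cfg$window_s <- sc$window_s
    i <- 0L
    for (cls in c("healthy", "schizophrenia")) {
      for (s in seq_len(sc$n_subjects_per_class)) {
        i <- i + 1L
        sid <- sprintf("%s_%02d", substr(cls, 1L, 2L), s)
        gr <- generate_recording(sc, class_label = cls,
                                 subject_seed = subject_seed_for(sc$seed, i),
                                 subject_id = sid)
        if (progress)
          message(sprintf("[%d/%d] %s", i, 2L * sc$n_subjects_per_class, sid))
        tables[[i]] <- process_recording(gr$recording, cfg, cls, sid)
      }
    }
  } else {
    p <- cfg$paths
    for (i in seq_along(p$files)) {
      rec <- read_recording(p$files[[i]],
                            fs_override = p$fs_override)
      sid <- if (!is.null(p$subject_ids)) p$subject_ids[[i]]
             else sprintf("s%02d", i)
      if (progress) message(sprintf("[%d/%d] %s", i, length(p$files), sid))
      tables[[i]] <- process_recording(rec, cfg, p$labels[[i]], sid)
    }
  }
  feats <- do.call(rbind, tables)
  if (cfg$selection$top_k > ncol(feats) - 2L)
    stop("top_k exceeds the extracted feature count", call. = FALSE)
  ranking <- rank_and_select(feats, k = cfg$selection$top_k)
  cl <- cfg$classifier
  cv <- crossvalidate(feats, spec = cl$spec, folds = cl$folds,
                      repeats = cl$repeats, seed = cl$seed,
                      selection = cfg$selection$scope,
                      top_k = cfg$selection$top_k,
                      groups = if (isTRUE(cl$subject_cv)) feats$subject_id)
  res <- structure(list(features = feats, ranking = ranking, cv = cv,
                        config = cfg, config_hash = hash),
                   class = "aleewr_pipeline")
  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(res, cfg$out_dir)
  res
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(res$features, file.path(out_dir, "features.csv"))
  write_ranked_features(res$ranking, file.path(out_dir, "anova_weights.csv"))
  m <- res$cv$metrics
  utils::write.table(
    data.frame(repeat_ = seq_len(nrow(m)), m,
               t(vapply(res$cv$per_repeat,
                        function(cm) unlist(cm[c("tp", "tn", "fp", "fn")]),
                        numeric(4)))),
    file.path(out_dir, "cv_report.csv"), sep = ",", row.names = FALSE,
    quote = FALSE)
  log <- c(sprintf("config_hash: %s", res$config_hash),
           utils::capture.output(utils::str(unclass(res$config))))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.aleewr_pipeline <- function(x, ...) {
  cat("<aleewr_pipeline> config", x$config_hash, "\n")
  cat(sprintf("  %d epochs x %d features\n", nrow(x$features),
              ncol(x$features) - 2L))
  print(x$cv)
  invisible(x)
}

#' @export
summary.aleewr_pipeline <- function(object, ...) {
  cat("Top-ranked features (global ANOVA):\n")
  print(object$ranking, n = object$ranking$k)
  summary(object$cv)
  invisible(object)
}
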