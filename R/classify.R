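# KNN variants and repeated stratified k-fold cross-validation.
#
# Three named presets mirror the common KNN configurations for this task:
# fine KNN (k = 1, Euclidean), weighted KNN (k = 100, squared-inverse
# distance voting) and cubic KNN (Minkowski order-3 distance, k = 10).

#' KNN classifier specification
#'
#' @param preset Optional named preset: `"fknn"` (k = 1, Euclidean,
#'   uniform), `"wknn"` (k = 100, Euclidean, squared-inverse weighting) or
#'   `"cknn"` (k = 10, Minkowski order 3, uniform). Individual arguments
#'   override the preset.
#' @param k Neighbour count (>= 1).
#' @param metric `"euclidean"` or `"minkowski_p3"`.
#' @param weighting `"uniform"` or `"squared_inverse"`.
#' @return Object of class `knn_spec`.
#' @export
#' @examples
#' knn_spec("fknn")
#' knn_spec(k = 5, metric = "minkowski_p3")
knn_spec <- function(preset = NULL, k = NULL, metric = NULL,
                     weighting = NULL) {
  base <- list(k = 1L, metric = "euclidean", weighting = "uniform",
               name = "knn")
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("fknn", "wknn", "cknn"))
    base <- switch(preset,
      fknn = list(k = 1L, metric = "euclidean", weighting = "uniform",
                  name = "FKNN"),
      wknn = list(k = 100L, metric = "euclidean",
                  weighting = "squared_inverse", name = "WKNN"),
      cknn = list(k = 10L, metric = "minkowski_p3", weighting = "uniform",
                  name = "CKNN"))
  }
  if (!is.null(k)) base$k <- as.integer(k)
  if (!is.null(metric))
    base$metric <- match.arg(metric, c("euclidean", "minkowski_p3"))
  if (!is.null(weighting))
    base$weighting <- match.arg(weighting, c("uniform", "squared_inverse"))
  if (base$k < 1L) stop("k must be >= 1", call. = FALSE)
  structure(base, class = "knn_spec")
}

#' @export
print.knn_spec <- function(x, ...) {
  cat(sprintf("<knn_spec> %s: k = %d, metric = %s, weighting = %s\n",
              x$name, x$k, x$metric, x$weighting))
  invisible(x)
}

knn_distances <- function(train_X, query, metric) {
  d <- sweep(train_X, 2L, query)
  if (metric == "euclidean") sqrt(rowSums(d^2))
  else rowSums(abs(d)^3)^(1 / 3)
}

#' Predict the label of one query point with KNN
#'
#' Finds the `k` nearest training rows (distance ties broken by training
#' index). Uniform weighting takes a majority vote, vote ties resolved by
#' the label of the tied-class neighbour with the smallest training index;
#' squared-inverse weighting sums `1/d^2` votes, a zero-distance neighbour
#' deciding outright. `k` larger than the training set is clipped with a
#' warning.
#'
#' @param train_X Numeric matrix of training rows.
#' @param train_y Label per training row.
#' @param spec A [knn_spec()].
#' @param query Numeric vector (one row's features).
#' @return Predicted label (character).
#' @export
knn_predict <- function(train_X, train_y, spec, query) {
  train_X <- as.matrix(train_X)
  train_y <- as.character(train_y)
  if (nrow(train_X) == 0L) stop("empty training set", call. = FALSE)
  k <- spec$k
  if (k > nrow(train_X)) {
    warning(sprintf("k = %d clipped to training size %d", k, nrow(train_X)))
    k <- nrow(train_X)
  }
  d <- knn_distances(train_X, as.numeric(query), spec$metric)
  nn <- order(d, seq_along(d))[seq_len(k)]
  if (spec$weighting == "squared_inverse") {
    zero <- nn[d[nn] < 1e-300]
    if (length(zero)) return(train_y[zero[1L]])
    w <- 1 / d[nn]^2
    votes <- tapply(w, train_y[nn], sum)
  } else {
    votes <- table(train_y[nn])
  }
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) return(top)
  # vote tie: label of the smallest-index neighbour among tied classes
  for (i in nn) if (train_y[i] %in% top) return(train_y[i])
  top[1L]
}

# batch prediction: one query per row
knn_predict_batch <- function(train_X, train_y, spec, Q) {
  apply(as.matrix(Q), 1L, function(q)
    knn_predict(train_X, train_y, spec, q))
}

#' Confusion matrix from counts
#'
#' @param tp,tn,fp,fn Non-negative counts, with the disease
#'   (schizophrenia) class as positive.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(v) <= 0) stop("empty confusion matrix", call. = FALSE)
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity (true-positive rate on the disease class),
#' specificity (true-negative rate on the healthy class) and precision,
#' as fractions in \[0, 1\]. A zero denominator yields `NaN`.
#'
#' @param cm A [confusion_matrix()] or a list/vector with `tp`, `tn`,
#'   `fp`, `fn`.
#' @return Named numeric vector
#'   `c(accuracy, sensitivity, specificity, precision)`.
#' @export
#' @examples
#' round(100 * confusion_metrics(confusion_matrix(tp = 500, tn = 502,
#'                                                fp = 2, fn = 4)), 2)
confusion_metrics <- function(cm) {
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  total <- tp + tn + fp + fn
  div <- function(a, b) if (b > 0) a / b else NaN
  c(accuracy = div(tp + tn, total),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    precision = div(tp, tp + fp))
}

stratified_folds <- function(labels, folds) {
  f <- factor(labels)
  assign <- integer(length(f))
  for (lv in levels(f)) {
    idx <- which(f == lv)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified k-fold cross-validation of a KNN classifier
#'
#' Per repeat: a fresh seeded stratified shuffle assigns every observation
#' to one of `folds` folds (class-wise sizes differ by at most one); each
#' fold in turn is held out, the classifier trained on the rest, and fold
#' confusions aggregated into one per-repeat confusion matrix. With
#' `selection = "fold"` the ANOVA top-`top_k` features are re-ranked inside
#' each training fold (no selection leakage); `"global"` ranks once on the
#' full table, the protocol that matches ranking-before-CV workflows.
#' Metrics are averaged over repeats. Deterministic for a fixed seed.
#'
#' @param X Feature matrix (observations in rows) or [feature_table()]
#'   data frame.
#' @param labels Class per row (two classes; taken from the data frame when
#'   omitted).
#' @param spec A [knn_spec()].
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeats (default 20).
#' @param seed Integer seed.
#' @param selection `"fold"`, `"global"` or `"none"` (use all features).
#' @param top_k Features kept by the ANOVA ranking (default 10).
#' @param positive Positive-class label (default `"schizophrenia"`; falls
#'   back to the second class level when absent).
#' @param groups Optional grouping id per row (e.g. subject). When given,
#'   folds are assigned at the group level so no group straddles a
#'   train/test split — the leakage-free subject-wise protocol.
#' @return Object of class `cv_report`.
#' @export
crossvalidate <- function(X, labels = NULL, spec = knn_spec("fknn"),
                          folds = 10L, repeats = 20L, seed = 1L,
                          selection = c("fold", "global", "none"),
                          top_k = 10L, positive = "schizophrenia",
                          groups = NULL) {
  selection <- match.arg(selection)
  if (is.data.frame(X)) {
    if (is.null(labels) && "label" %in% names(X)) labels <- X$label
    X <- as.matrix(X[, setdiff(names(X), c("label", "subject_id")),
                     drop = FALSE])
  }
  labels <- as.character(labels)
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("two-class labels required", call. = FALSE)
  if (min(table(f)) < folds)
    stop("smallest class has fewer observations than folds", call. = FALSE)
  if (!is.null(groups)) {
    groups <- as.character(groups)
    gl <- unique(cbind(groups, labels))
    if (min(table(gl[, 2L])) < folds)
      stop("smallest class has fewer groups than folds", call. = FALSE)
  }
  if (selection != "none") {
    if (top_k > ncol(X))
      stop(sprintf("top_k = %d exceeds the %d available features",
                   top_k, ncol(X)), call. = FALSE)
  }
  if (!positive %in% levels(f)) positive <- levels(f)[2L]
  negative <- setdiff(levels(f), positive)[1L]

  if (selection == "global")
    global_sel <- rank_and_select(X, labels, k = top_k)$selected

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  per_repeat <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    if (is.null(groups)) {
      assign <- stratified_folds(labels, folds)
    } else {
      g <- unique(groups)
      glab <- labels[match(g, groups)]
      gfold <- stratified_folds(glab, folds)
      assign <- gfold[match(groups, g)]
    }
    tp <- tn <- fp <- fn <- 0L
    for (fold in seq_len(folds)) {
      te <- which(assign == fold)
      tr <- which(assign != fold)
      cols <- switch(selection,
        none = seq_len(ncol(X)),
        global = global_sel,
        fold = rank_and_select(X[tr, , drop = FALSE], labels[tr],
                               k = top_k)$selected)
      pred <- knn_predict_batch(X[tr, cols, drop = FALSE], labels[tr],
                                spec, X[te, cols, drop = FALSE])
      truth <- labels[te]
      tp <- tp + sum(pred == positive & truth == positive)
      tn <- tn + sum(pred == negative & truth == negative)
      fp <- fp + sum(pred == positive & truth == negative)
      fn <- fn + sum(pred == negative & truth == positive)
    }
    per_repeat[[r]] <- confusion_matrix(tp = tp, tn = tn, fp = fp, fn = fn)
  }
  mets <- t(vapply(per_repeat, confusion_metrics, numeric(4)))
  structure(list(per_repeat = per_repeat,
                 metrics = mets,
                 accuracy = mean(mets[, "accuracy"]),
                 sensitivity = mean(mets[, "sensitivity"]),
                 specificity = mean(mets[, "specificity"]),
                 precision = mean(mets[, "precision"]),
                 scheme = list(folds = folds, repeats = repeats, seed = seed,
                               selection = selection, top_k = top_k,
                               spec = spec, positive = positive,
                               n_obs = nrow(X))),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$scheme
  cat(sprintf("<cv_report> %s, %d-fold x %d repeats (seed %d, selection %s)\n",
              s$spec$name, s$folds, s$repeats, s$seed, s$selection))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  m <- object$metrics
  out <- data.frame(metric = colnames(m),
                    mean = colMeans(m),
                    sd = apply(m, 2L, stats::sd))
  rownames(out) <- NULL
  cat(sprintf("Repeated stratified %d-fold cross-validation (%d repeats, %d observations)\n",
              object$scheme$folds, object$scheme$repeats,
              object$scheme$n_obs))
  print(out, row.names = FALSE)
  invisible(out)
}
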