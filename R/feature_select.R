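# One-way ANOVA F-statistic feature weights and top-k ranking. The total
# sum of squares of each feature column is partitioned into a between-class
# part (SSR) and a within-class part (SSE); the weight is the F ratio
# F = (SSR / (k - 1)) / (SSE / (n - k)). A feature that separates the
# classes perfectly (SSE = 0, SSR > 0) receives an +Inf sentinel and ranks
# above every finite weight.

#' ANOVA F weight of a single feature column
#'
#' @param column Numeric vector of feature values.
#' @param labels Class label per observation (2 or more classes, each with
#'   at least 2 observations).
#' @return Scalar F statistic; `Inf` when the within-class variation is
#'   zero but classes differ, `0` when class means are identical.
#' @export
#' @examples
#' anova_weight(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
anova_weight <- function(column, labels) {
  as.numeric(anova_weights(matrix(as.numeric(column), ncol = 1L), labels))
}

#' ANOVA F weights for every column of a feature matrix
#'
#' Vectorised over columns; see [anova_weight()] for the statistic.
#'
#' @param X Numeric matrix, observations in rows.
#' @param labels Class label per row.
#' @return Named numeric vector of F weights (one per column).
#' @export
anova_weights <- function(X, labels) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("feature matrix contains non-finite values",
                               call. = FALSE)
  f <- factor(labels)
  if (nlevels(f) < 2L) stop("need at least 2 classes", call. = FALSE)
  nj <- table(f)
  if (any(nj < 2L))
    stop(sprintf("every class needs >= 2 observations (got %s)",
                 paste(sprintf("%s=%d", names(nj), nj), collapse = ", ")),
         call. = FALSE)
  if (nrow(X) != length(f))
    stop("nrow(X) must equal length(labels)", call. = FALSE)
  n <- nrow(X); k <- nlevels(f)
  grand <- colMeans(X)
  # class means: k x p
  M <- rowsum(X, f) / as.numeric(nj)
  ssr <- colSums(as.numeric(nj) * (M - rep(grand, each = k))^2)
  sst <- colSums((X - rep(grand, each = n))^2)
  sse <- pmax(sst - ssr, 0)
  fstat <- numeric(ncol(X))
  msr <- ssr / (k - 1)
  mse <- sse / (n - k)
  zero_sse <- sse <= 1e-12 * pmax(sst, 1)
  ok <- !zero_sse
  fstat[ok] <- msr[ok] / mse[ok]
  fstat[zero_sse & ssr > 0] <- Inf
  fstat[ssr <= 0] <- 0
  names(fstat) <- colnames(X)
  fstat
}

#' Rank features by ANOVA F weight and keep the top k
#'
#' Descending stable sort of the per-column F weights (ties keep the lower
#' column index first; `Inf` sentinels rank above all finite weights).
#'
#' @param X Numeric feature matrix (observations in rows) or a data frame
#'   from [feature_table()] (its `label`/`subject_id` columns are used and
#'   removed).
#' @param labels Class per row; taken from a feature-table data frame when
#'   omitted.
#' @param k Number of features to keep (default 10).
#' @return Object of class `ranked_features`: list with `weights`, `order`
#'   (all columns, by descending weight), `selected` (top-k column
#'   indices), `names`.
#' @export
rank_and_select <- function(X, labels = NULL, k = 10L) {
  if (is.data.frame(X)) {
    if (is.null(labels) && "label" %in% names(X)) labels <- X$label
    X <- as.matrix(X[, setdiff(names(X), c("label", "subject_id")),
                     drop = FALSE])
  }
  if (is.null(labels)) stop("'labels' is required", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > ncol(X))
    stop(sprintf("k must lie in [1, %d]", ncol(X)), call. = FALSE)
  w <- anova_weights(X, labels)
  ord <- order(-w, seq_along(w))      # descending, stable: lower index first
  structure(list(weights = w, order = ord, selected = ord[seq_len(k)],
                 names = colnames(X), k = k),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, n = 10L, ...) {
  cat(sprintf("<ranked_features> %d features, top %d selected\n",
              length(x$weights), x$k))
  top <- x$order[seq_len(min(n, length(x$order)))]
  nm <- if (is.null(x$names)) as.character(top) else x$names[top]
  for (i in seq_along(top))
    cat(sprintf("  %2d. %-8s F = %.4f\n", i, nm[i], x$weights[top[i]]))
  invisible(x)
}

#' Write a ranked-weights report
#'
#' Delimited text with columns feature, weight, rank.
#'
#' @param rf A [rank_and_select()] result.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_ranked_features <- function(rf, path, sep = ",") {
  stopifnot(inherits(rf, "ranked_features"))
  nm <- if (is.null(rf$names)) as.character(rf$order) else rf$names[rf$order]
  df <- data.frame(feature = nm, weight = rf$weights[rf$order],
                   rank = seq_along(rf$order))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
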