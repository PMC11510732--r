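test_that("knn presets carry the documented parameters", {
  f <- knn_spec("fknn"); w <- knn_spec("wknn"); c3 <- knn_spec("cknn")
  expect_equal(f$k, 1L); expect_equal(f$metric, "euclidean")
  expect_equal(w$k, 100L); expect_equal(w$weighting, "squared_inverse")
  expect_equal(c3$metric, "minkowski_p3")
})

test_that("single-point training sets and resubstitution behave", {
  expect_warning(
    lab <- knn_predict(matrix(0, 1, 2), "h", knn_spec(k = 3), c(9, 9)),
    "clipped")
  expect_identical(lab, "h")

  set.seed(101)
  X <- matrix(rnorm(40), 20)
  y <- rep(c("healthy", "schizophrenia"), 10)
  pred <- vapply(seq_len(20), function(i)
    knn_predict(X, y, knn_spec("fknn"), X[i, ]), character(1))
  expect_identical(pred, y)
})

test_that("squared-inverse weighting matches the hand-computed vote", {
  X <- matrix(c(0, 1, 10), ncol = 1)
  y <- c("H", "H", "SZ")
  spec <- knn_spec(k = 3, weighting = "squared_inverse")
  # distances from 2: 2, 1, 8 -> weights 1/4, 1, 1/64 -> H
  expect_identical(knn_predict(X, y, spec, 2), "H")
  # brute-force oracle over a grid of queries
  for (q in c(-1, 0.5, 3, 7, 9.4)) {
    d2 <- (X[, 1] - q)^2
    w <- 1 / d2
    oracle <- if (sum(w[y == "H"]) >= sum(w[y == "SZ"])) "H" else "SZ"
    expect_identical(knn_predict(X, y, spec, q), oracle)
  }
  # zero distance decides outright
  expect_identical(knn_predict(X, y, spec, 10), "SZ")
})

test_that("fine KNN agrees with an independent 1-NN implementation", {
  skip_if_not_installed("class")
  set.seed(102)
  tr <- matrix(rnorm(60), 30); te <- matrix(rnorm(20), 10)
  y <- sample(c("a", "b"), 30, replace = TRUE)
  ours <- vapply(seq_len(10), function(i)
    knn_predict(tr, y, knn_spec("fknn"), te[i, ]), character(1))
  ref <- as.character(class::knn(tr, te, y, k = 1))
  expect_identical(ours, ref)
})

test_that("confusion metrics reproduce printed-count arithmetic", {
  m <- confusion_metrics(confusion_matrix(tp = 500, tn = 502, fp = 2,
                                          fn = 4))
  expect_equal(round(100 * m[["accuracy"]], 2), 99.40)
  expect_equal(round(100 * m[["sensitivity"]], 2), 99.21)
  expect_equal(round(100 * m[["specificity"]], 2), 99.60)

  perfect <- confusion_metrics(confusion_matrix(tp = 1, tn = 1, fp = 0,
                                                fn = 0))
  expect_true(all(perfect == 1))

  none <- confusion_metrics(list(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_true(is.nan(none[["sensitivity"]]))
})

test_that("stratified folds partition rows with near-equal sizes", {
  set.seed(103)
  y <- rep(c("healthy", "schizophrenia"), c(53, 47))
  X <- matrix(rnorm(100 * 3), 100)
  cv <- crossvalidate(X, y, knn_spec("fknn"), folds = 10, repeats = 2,
                      seed = 5, selection = "none")
  for (cm in cv$per_repeat)
    expect_equal(cm$tp + cm$tn + cm$fp + cm$fn, 100)
  # direct check of the fold assigner
  set.seed(1)
  assign <- aleewr:::stratified_folds(y, 10)
  expect_length(assign, 100)
  sizes <- table(assign)
  expect_lte(max(sizes) - min(sizes), 2)  # <=1 per class, 2 classes
  for (cl in unique(y)) {
    cs <- table(assign[y == cl])
    expect_lte(max(cs) - min(cs), 1)
  }
})

test_that("separable blobs are classified perfectly, null labels at chance", {
  set.seed(104)
  n <- 60
  X <- rbind(matrix(rnorm(n * 2, 0, 0.3), n),
             matrix(rnorm(n * 2, 10, 0.3), n))
  y <- rep(c("healthy", "schizophrenia"), each = n)
  cv <- crossvalidate(X, y, knn_spec("fknn"), folds = 10, repeats = 3,
                      seed = 7, selection = "none")
  expect_equal(cv$accuracy, 1.0)

  yn <- sample(y)                           # labels shuffled: no signal
  cvn <- crossvalidate(X[, , drop = FALSE], yn, knn_spec("fknn"),
                       folds = 10, repeats = 20, seed = 8,
                       selection = "none")
  se <- sqrt(0.25 / (2 * n))
  expect_lt(abs(cvn$accuracy - 0.5), 3 * se)
})

test_that("cross-validation is deterministic for a fixed seed", {
  set.seed(105)
  X <- matrix(rnorm(80 * 4), 80)
  y <- rep(c("a", "b"), 40)
  cv1 <- crossvalidate(X, y, knn_spec("fknn"), folds = 5, repeats = 3,
                       seed = 11, selection = "none")
  cv2 <- crossvalidate(X, y, knn_spec("fknn"), folds = 5, repeats = 3,
                       seed = 11, selection = "none")
  expect_identical(cv1$metrics, cv2$metrics)
  expect_error(crossvalidate(X[1:8, ], y[1:8], folds = 10,
                             selection = "none"), "fewer")
})

test_that("grouped folds keep whole subjects on one side of the split", {
  set.seed(106)
  groups <- rep(sprintf("s%02d", 1:20), each = 5)
  y <- rep(rep(c("healthy", "schizophrenia"), each = 10), each = 5)
  X <- matrix(rnorm(100 * 2), 100)
  g <- unique(groups)
  glab <- y[match(g, groups)]
  set.seed(2)
  gfold <- aleewr:::stratified_folds(glab, 5)
  assign <- gfold[match(groups, g)]
  for (s in g)
    expect_length(unique(assign[groups == s]), 1L)
  cv <- crossvalidate(X, y, knn_spec("fknn"), folds = 5, repeats = 2,
                      seed = 3, selection = "none", groups = groups)
  expect_s3_class(cv, "cv_report")
})
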