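# two independent non-Gaussian sources and a fixed mixing matrix; the
# recovery oracle correlates every estimated source against every true one
# and asserts a perfect matching exists
recovery_ok <- function(S_true, S_est, thresh) {
  co <- abs(stats::cor(t(S_true), t(S_est)))
  # greedy matching is exact for 2 sources
  best <- apply(co, 1L, max)
  all(best > thresh) && length(unique(apply(co, 1L, which.max))) == nrow(co)
}

make_sources <- function(n = 4000, seed = 3) {
  set.seed(seed)
  rbind(runif(n, -1, 1),
        rexp(n) * sample(c(-1, 1), n, replace = TRUE))
}

test_that("FastICA recovers two mixed non-Gaussian sources for any seed", {
  S <- make_sources()
  X <- matrix(c(1, 0.5, 0.5, 1), 2) %*% S
  for (seed in c(1, 7, 99)) {
    m <- fit_fastica(X, seed = seed)
    expect_true(m$converged)
    expect_true(recovery_ok(S, m$sources, 0.95))
  }
})

test_that("an orthogonal mixture of whitened sources is recovered tightly", {
  S <- make_sources(seed = 8)
  Sw <- (S - rowMeans(S)) / sqrt(rowMeans((S - rowMeans(S))^2))
  th <- pi / 5
  Q <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  m <- fit_fastica(Q %*% Sw, seed = 2)
  expect_true(recovery_ok(Sw, m$sources, 0.99))
})

test_that("the rotation has orthonormal rows and unit-variance sources", {
  S <- make_sources(seed = 5)
  m <- fit_fastica(matrix(c(1, 0.3, 0.2, 1), 2) %*% S, seed = 4)
  WWt <- m$rotation %*% t(m$rotation)
  expect_lt(max(abs(WWt - diag(2))), 1e-8)
  expect_equal(unname(apply(m$sources, 1, function(s) mean(s^2) - mean(s)^2)),
               c(1, 1), tolerance = 1e-6)
})

test_that("a fixed seed gives bit-identical sources across runs", {
  S <- make_sources(seed = 9)
  X <- matrix(c(1, 0.5, 0.5, 1), 2) %*% S
  m1 <- fit_fastica(X, seed = 42)
  m2 <- fit_fastica(X, seed = 42)
  expect_identical(m1$sources, m2$sources)
})

test_that("rank-deficient input fails at whitening", {
  x <- rnorm(500)
  expect_error(fit_fastica(rbind(x, 2 * x), seed = 1), "rank-deficient")
})

test_that("kurtosis flagging isolates a sparse spike train", {
  set.seed(31)
  n <- 3000
  S <- rbind(matrix(rnorm(5 * n), 5),
             {
               s <- numeric(n); s[sample.int(n, 12)] <- 8; s
             })
  fake <- structure(list(sources = S), class = "fastica")
  flags <- flag_artifact_components(fake)
  expect_identical(as.integer(flags), 6L)
  ku <- attr(flags, "kurtosis")
  expect_gt(ku[6], 20)

  gauss <- structure(list(sources = matrix(rnorm(5 * n), 5)),
                     class = "fastica")
  expect_length(flag_artifact_components(gauss), 0L)
  expect_length(flag_artifact_components(fake, kurtosis_z = Inf), 0L)
})

test_that("dropping no components reconstructs the input losslessly", {
  set.seed(32)
  X <- matrix(c(1, 0.4, 0.3, 1), 2) %*% make_sources(seed = 12)
  m <- fit_fastica(X, seed = 3)
  back <- remove_components(m, integer(0))
  rel <- sqrt(rowSums((back - X)^2) / rowSums(X^2))
  expect_lt(max(rel), 1e-8)
  expect_error(remove_components(m, 1:2), "every component")
})

test_that("removing the flagged blink component cleans frontal channels", {
  # 5 bursty AR brain sources mixed into 6 channels plus one blink source
  # on the frontal channels: a square, identifiable ICA model whose
  # ground-truth parts the generator retains
  set.seed(33)
  n <- 5000; fs <- 250
  ar <- function() {
    a <- c(2 * 0.97 * cos(2 * pi * 10 / fs), -0.97^2)
    x <- as.numeric(stats::filter(rnorm(n), a, method = "recursive"))
    e <- as.numeric(stats::filter(rnorm(n), 0.995, method = "recursive"))
    x <- x * (1 + 0.8 * abs(e) / sd(e))   # mild amplitude modulation
    x / sd(x)
  }
  S <- t(sapply(1:5, function(i) ar()))
  A <- matrix(runif(6 * 5, 0.2, 1), 6, 5)
  brain <- A %*% S                        # noise-free brain content
  blink <- numeric(n)
  for (cc in seq(700, n - 200, by = 1600)) {
    idx <- cc + 0:99
    blink[idx] <- blink[idx] + sin(pi * (1:100) / 101)^2
  }
  topo <- c(1, 1, 0.6, 0, 0, 0)          # frontal channels 1-3 only
  X <- brain + 8 * (topo %o% blink)
  m <- fit_fastica(X, seed = 11)
  flags <- flag_artifact_components(m)
  expect_gte(length(flags), 1L)
  clean <- remove_components(m, flags)
  for (ch in 1:2) {
    expect_lt(abs(cor(clean[ch, ], blink)), 0.2)
    expect_gt(abs(cor(clean[ch, ], brain[ch, ])), 0.9)
  }
})

test_that("one-call cleanup returns the input untouched when disabled", {
  ep <- noise_epoch(nc = 3, n = 600, seed = 41)
  expect_identical(clean_artifacts(ep, enabled = FALSE), ep)
})
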