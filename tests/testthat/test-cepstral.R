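test_that("the cepstrum of a unit impulse is identically zero", {
  expect_equal(as.numeric(real_cepstrum(c(1, 0, 0, 0))), rep(0, 4))
})

test_that("the cepstrum matches the naive O(N^2) DFT oracle", {
  expect_equal(as.numeric(real_cepstrum(c(1, 0.5, 0, 0))),
               naive_real_cepstrum(c(1, 0.5, 0, 0)), tolerance = 1e-10)
  set.seed(71)
  for (n in c(16, 100, 256)) {
    x <- rnorm(n)
    expect_equal(as.numeric(real_cepstrum(x)), naive_real_cepstrum(x),
                 tolerance = 1e-10)
  }
})

test_that("positive gain shifts only the quefrency-zero coefficient", {
  set.seed(72)
  x <- rnorm(128)
  c1 <- as.numeric(real_cepstrum(x))
  c2 <- as.numeric(real_cepstrum(3.5 * x))
  expect_equal(c2[-1], c1[-1], tolerance = 1e-10)
  expect_equal(c2[1] - c1[1], log(3.5), tolerance = 1e-10)
  expect_error(real_cepstrum(numeric(64)), "degenerate")
})

test_that("the cepstrum is invariant to circular time shifts", {
  set.seed(73)
  x <- rnorm(200)
  c0 <- as.numeric(real_cepstrum(x))
  for (s in c(1, 17, 99)) {
    xs <- c(x[(s + 1):200], x[1:s])
    expect_equal(as.numeric(real_cepstrum(xs)), c0, tolerance = 1e-9)
  }
})

test_that("cepstral activity is the population variance", {
  expect_equal(cepstral_activity(rep(2.5, 10)), 0)
  expect_equal(cepstral_activity(c(1, -1, 1, -1)), 1)
  set.seed(74)
  v <- rnorm(500)
  expect_equal(cepstral_activity(v), naive_pop_var(v), tolerance = 1e-12)
  expect_equal(cepstral_activity(4 * v), 16 * cepstral_activity(v),
               tolerance = 1e-9)
})

test_that("cepstral mobility follows the Hjorth square-root convention", {
  expect_equal(cepstral_mobility(c(0, 1, 2, 3, 4)), 0)
  set.seed(75)
  v <- rnorm(100)
  expect_equal(cepstral_mobility(3 * v), cepstral_mobility(v),
               tolerance = 1e-12)
  c6 <- c(0, 1, 0, 1, 0, 1)
  expect_equal(cepstral_mobility(c6),
               sqrt(naive_pop_var(diff(c6)) / naive_pop_var(c6)))
  # the literal no-radical reading is one switch away
  expect_equal(cepstral_mobility(c6, sqrt = FALSE),
               cepstral_mobility(c6)^2)
  expect_error(cepstral_mobility(rep(1, 5)), "zero activity")
})

test_that("complexity is scale-free, ~1 for a sinusoid, higher for noise", {
  set.seed(76)
  v <- rnorm(80)
  expect_equal(cepstral_complexity(5 * v), cepstral_complexity(v),
               tolerance = 1e-12)
  n <- 1000
  sine <- sin(2 * pi * 7 * (0:(n - 1)) / n)   # 7 whole periods
  expect_lt(abs(cepstral_complexity(sine) - 1), 0.05)
  # a random walk is smooth but its increments are white, so its
  # mobility is tiny while its derivative's is not: complexity of the
  # walk dwarfs that of white noise (direct evaluation of both ratios)
  walk <- cumsum(rnorm(600))
  white <- rnorm(600)
  expect_gt(cepstral_complexity(walk), cepstral_complexity(white))
  expect_gt(cepstral_complexity(white), 1)
})

test_that("feature extraction yields 3 named features per channel", {
  ep <- noise_epoch(nc = 19, n = 2000, seed = 77)
  fv <- extract_features(ep)
  expect_length(fv, 57L)
  expect_identical(names(fv)[1:3], c("AFp1", "MFp1", "CFp1"))
  expect_identical(names(fv)[55:57], c("AO2", "MO2", "CO2"))
  expect_true(all(is.finite(fv)))

  small <- extract_features(noise_epoch(nc = 2, n = 500, seed = 78))
  expect_length(small, 6L)

  set.seed(79)
  x <- rnorm(500)
  dup <- extract_features(epoch(rbind(x, x), fs = 250,
                                channel_labels = c("a", "b")))
  expect_equal(unname(dup[1:3]), unname(dup[4:6]))
})

test_that("normalised inputs make all three features gain-invariant", {
  ep <- noise_epoch(nc = 2, n = 800, seed = 80)
  scaled <- ep; scaled$data <- 7 * ep$data
  f1 <- extract_features(normalize_gain(ep))
  f2 <- extract_features(normalize_gain(scaled))
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("feature tables carry labels and subject ids per epoch", {
  eps <- epoch_set(list(noise_epoch(seed = 81, label = "healthy"),
                        noise_epoch(seed = 82, label = "schizophrenia")))
  df <- feature_table(eps)
  expect_equal(dim(df), c(2L, 11L))
  expect_identical(df$label, c("healthy", "schizophrenia"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(df, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back[[1]], df[[1]], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(names(back), names(df))
})
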