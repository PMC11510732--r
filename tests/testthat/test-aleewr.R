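test_that("log energy matches direct evaluation and floors at zero", {
  expect_equal(log_energy(c(1, 1)), log(2))
  expect_equal(log_energy(numeric(100)), log(1e-300))
  set.seed(61)
  x <- rnorm(5000)
  s <- 0
  for (v in x) s <- s + v * v          # naive loop oracle
  expect_equal(log_energy(x), log(s), tolerance = 1e-12)
})

test_that("mode selection follows the min-max normalised threshold rule", {
  one <- select_modes(3.3)
  expect_identical(one$selected, 1L)

  eq <- select_modes(c(3.2, 3.2, 3.2))
  expect_identical(eq$selected, 1:3)
  expect_equal(eq$normalized, c(1, 1, 1))

  le <- c(0, 5, 10)
  sm <- select_modes(le, threshold = 0.10)
  # independent normalisation oracle
  expect_equal(sm$normalized, (le - min(le)) / diff(range(le)))
  expect_identical(sm$selected, c(2L, 3L))

  expect_error(select_modes(c(1, 2), threshold = 0), "threshold")
})

test_that("selection is monotone in the threshold and keeps the argmax", {
  set.seed(62)
  for (i in 1:20) {
    le <- rnorm(6)
    prev <- NULL
    for (th in c(0.9, 0.5, 0.2, 0.05, 0.001)) {
      sel <- select_modes(le, threshold = th)$selected
      expect_true(which.max(le) %in% sel)
      if (!is.null(prev)) expect_true(all(prev %in% sel))
      prev <- sel
    }
  }
})

test_that("reconstruction sums exactly the selected modes", {
  x <- two_tone(5, 40)
  bank <- build_filter_bank(15, 5000, 250)
  md <- ewt_decompose(x, bank)
  full <- reconstruct_modes(md, 1:2)
  expect_lt(sqrt(sum((full - x)^2) / sum(x^2)), 1e-6)
  expect_identical(reconstruct_modes(md, 2L), as.numeric(md$modes[, 2]))
  low <- reconstruct_modes(md, 1L)
  expect_lt(band_energy_fraction(low, 250, 15.0001, 125), 0.01)
  expect_error(reconstruct_modes(md, integer(0)), "non-empty")
  expect_error(reconstruct_modes(md, 5L), "range")
})

test_that("the per-epoch chain keeps shape and attaches channel reports", {
  ep <- normalize_gain(noise_epoch(nc = 19, n = 5000, seed = 63))
  out <- aleewr_process(ep)
  expect_equal(dim(out$data), c(19L, 5000L))
  rep_ <- attr(out, "aleewr_report")
  expect_length(rep_, 19L)
  expect_true(all(vapply(rep_, function(r) length(r$selected) >= 1,
                         logical(1))))
})

test_that("a dominant tone survives a high threshold nearly intact", {
  x <- two_tone(10, 60, a1 = sqrt(99), a2 = 1)   # 99% energy at 10 Hz
  ep <- normalize_gain(epoch(rbind(x, x), fs = 250))
  out <- aleewr_process(ep, threshold = 0.99)
  frac <- band_energy_fraction(out$data[1, ], 250, 8, 12)
  expect_gt(frac, 0.99)
  expect_gt(sum(out$data[1, ]^2) / sum(ep$data[1, ]^2), 0.9)
})

test_that("the chain is deterministic and selection-limited in energy", {
  ep <- normalize_gain(noise_epoch(nc = 2, n = 2000, seed = 64))
  o1 <- aleewr_process(ep)
  o2 <- aleewr_process(ep)
  expect_identical(o1$data, o2$data)

  # selected-mode energy never exceeds the full reconstruction's
  x <- ep$data[1, ]
  pk <- suppressWarnings(detect_spectral_maxima(x, 250, 5))
  bank <- build_filter_bank(compute_boundaries(pk), 2000, 250)
  md <- ewt_decompose(x, bank)
  le <- apply(md$modes, 2, log_energy)
  sel <- select_modes(le)$selected
  e_sel <- sum(reconstruct_modes(md, sel)^2)
  e_full <- sum(reconstruct_modes(md, seq_along(le))^2)
  expect_lte(e_sel, e_full + 1e-9)
})

test_that("threshold approaching zero recovers the input", {
  # in the energy-share basis every nonzero mode's score is strictly
  # positive, so a vanishing threshold selects all modes and the
  # reconstruction converges to the input; under min-max the weakest
  # mode's score is exactly 0 and stays excluded for any positive
  # threshold, so only near-completeness is required there
  ep <- normalize_gain(noise_epoch(nc = 2, n = 1500, seed = 65))
  out <- aleewr_process(ep, threshold = 1e-12, basis = "energy_share")
  rel <- sqrt(rowSums((out$data - ep$data)^2) / rowSums(ep$data^2))
  expect_lt(max(rel), 1e-6)

  mm <- aleewr_process(ep, threshold = 1e-12, basis = "minmax")
  relmm <- sqrt(rowSums((mm$data - ep$data)^2) / rowSums(ep$data^2))
  expect_lt(max(relmm), 0.5)
})

test_that("energy-share basis is available as the alternative reading", {
  le <- log(c(1, 99))                     # energies 1 and 99
  sm <- select_modes(le, threshold = 0.10, basis = "energy_share")
  expect_identical(sm$selected, 2L)       # mode 1 holds 1% of total energy
  sm2 <- select_modes(le, threshold = 0.005, basis = "energy_share")
  expect_identical(sm2$selected, 1:2)
})

test_that("an all-zero channel passes through with a warning", {
  m <- rbind(rnorm(1000), numeric(1000))
  expect_warning(out <- aleewr_process(m, fs = 250), "all-zero")
  expect_true(all(out[2, ] == 0))
})
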