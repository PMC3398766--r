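test_that("a constant spectrogram has all modulation amplitude at DC", {
  spec <- make_test_spec(matrix(3, 16, 20))
  mps <- compute_mps(spec)
  dc <- c(which.min(abs(mps$wf)), which.min(abs(mps$wt)))
  expect_equal(mps$amplitude[dc[1], dc[2]], 3 * 16 * 20, tolerance = 1e-10)
  off_dc <- mps$amplitude
  off_dc[dc[1], dc[2]] <- 0
  expect_lt(max(off_dc), 1e-8)
})

test_that("compute_mps matches a brute-force 2-D DFT to machine precision", {
  set.seed(21)
  V <- matrix(rnorm(8 * 6), 8, 6)
  spec <- make_test_spec(V, df = 10, dt = 0.002)
  mps <- compute_mps(spec)
  oracle <- brute_force_mps(V, df = 10, dt = 0.002)
  expect_equal(mps$wf, oracle$wf, tolerance = 1e-12)
  expect_equal(mps$wt, oracle$wt, tolerance = 1e-12)
  achieved <- mps$amplitude * exp(1i * mps$phase)
  expect_lt(max(Mod(achieved - oracle$Fm)) / max(Mod(oracle$Fm)), 1e-10)
})

test_that("a time-constant frequency ripple peaks at its ripple density", {
  # ripple at 2 cycles/kHz = 0.002 cycles/Hz over bins spaced 10 Hz
  nf <- 50; nt <- 12; df <- 10
  V <- matrix(cos(2 * pi * 0.002 * (0:(nf - 1)) * df), nf, nt)
  mps <- compute_mps(make_test_spec(V, df = df))
  marg <- rowSums(mps$amplitude)
  peaks <- mps$wf[order(marg, decreasing = TRUE)[1:2]]
  expect_equal(sort(peaks), c(-2, 2), tolerance = 0.1)
})

test_that("modulation spectra of real spectrograms are Hermitian", {
  set.seed(22)
  V <- matrix(rnorm(12 * 10), 12, 10)
  mps <- compute_mps(make_test_spec(V))
  # amplitude(-wf,-wt) = amplitude(wf,wt), phase antisymmetric, checked
  # on the subgrid that has a mirror partner
  nf <- length(mps$wf); nt <- length(mps$wt)
  i0 <- which.min(abs(mps$wf)); j0 <- which.min(abs(mps$wt))
  for (di in -3:3) for (dj in -3:3) {
    i <- i0 + di; j <- j0 + dj; im <- i0 - di; jm <- j0 - dj
    expect_equal(mps$amplitude[i, j], mps$amplitude[im, jm],
                 tolerance = 1e-10)
    if (mps$amplitude[i, j] > 1e-8)
      expect_equal(mps$phase[i, j], -mps$phase[im, jm], tolerance = 1e-8)
  }
})

test_that("mask presets implement the study cutoffs", {
  wt <- seq(-20, 20, by = 2)   # Hz
  wf <- seq(-4, 4, by = 0.5)   # cycles/kHz
  animal <- make_mask(animal_preset(), wt, wf)
  expect_equal(animal$keep[wf == 2, ], rep(0, length(wt)))
  expect_equal(animal$keep[wf == 0.5, ], rep(1, length(wt)))
  tool <- make_mask(tool_preset(), wt, wf)
  expect_equal(tool$keep[, wt == 2], rep(1, length(wf)))
  expect_equal(tool$keep[, wt == 8], rep(0, length(wf)))
  # DC is always kept, masks are symmetric in both axes
  expect_equal(animal$keep[wf == 0, wt == 0], 1)
  expect_identical(animal$keep, animal$keep[rev(seq_along(wf)),
                                            rev(seq_along(wt))])
})

test_that("an out-of-range cutoff warns and keeps everything", {
  expect_warning(
    m <- make_mask(filter_spec("lowpass_temporal", 1000),
                   seq(-20, 20, 2), seq(-4, 4, 0.5)),
    "exceeds")
  expect_true(all(m$keep == 1))
})

test_that("mask application is an exact idempotent projection", {
  set.seed(23)
  mps <- compute_mps(make_test_spec(matrix(rnorm(30 * 24), 30, 24)))
  mask <- make_mask(tool_preset(), mps$wt, mps$wf)
  once <- apply_mask(mps, mask)
  twice <- apply_mask(once, mask)
  expect_identical(once$amplitude, twice$amplitude)
  expect_identical(once$phase, twice$phase)
  # identity mask leaves the MPS bitwise unchanged
  ident <- make_mask(filter_spec("none"), mps$wt, mps$wf)
  expect_identical(apply_mask(mps, ident)$amplitude, mps$amplitude)
  # total squared amplitude after masking = sum over kept cells (oracle)
  expect_equal(sum(once$amplitude^2),
               sum((mps$amplitude^2)[mask$keep == 1]), tolerance = 1e-12)
  expect_lte(sum(once$amplitude^2), sum(mps$amplitude^2))
})

test_that("invert_mps round-trips a spectrogram to machine precision", {
  set.seed(24)
  spec <- make_test_spec(matrix(rnorm(20 * 16, sd = 0.5), 20, 16))
  back <- invert_mps(compute_mps(spec))
  expect_equal(back$values, spec$values, tolerance = 1e-10)
  expect_equal(back$freq, spec$freq)
  expect_equal(back$time, spec$time)
})

test_that("the spectral low-pass removes a planted ripple", {
  nf <- 50; nt <- 12; df <- 10
  V <- 2 + matrix(cos(2 * pi * 0.002 * (0:(nf - 1)) * df), nf, nt)
  spec <- make_test_spec(V, df = df)
  mps <- compute_mps(spec)
  filt <- apply_mask(mps, make_mask(animal_preset(), mps$wt, mps$wf))
  out <- invert_mps(filt)
  # the only non-DC component sat at 2 cycles/kHz and has been zeroed
  expect_lt(max(out$values) - min(out$values), 0.05)
  expect_equal(mean(out$values), mean(V), tolerance = 1e-8)
})

test_that("a DC-only modulation spectrum inverts to a constant", {
  spec <- make_test_spec(matrix(rnorm(10 * 8), 10, 8))
  mps <- compute_mps(spec)
  dc <- c(which.min(abs(mps$wf)), which.min(abs(mps$wt)))
  mps$amplitude[-dc[1], ] <- 0
  mps$amplitude[, -dc[2]] <- 0
  mps$phase[-dc[1], ] <- 0
  mps$phase[, -dc[2]] <- 0
  out <- invert_mps(mps)
  expect_equal(max(out$values), min(out$values), tolerance = 1e-10)
  expect_equal(mean(out$values), mean(spec$values), tolerance = 1e-10)
})

test_that("non-Hermitian modulation spectra are rejected", {
  spec <- make_test_spec(matrix(rnorm(10 * 8), 10, 8))
  mps <- compute_mps(spec)
  bad <- mps
  bad$phase[2, 3] <- bad$phase[2, 3] + 2  # break conjugate symmetry
  expect_error(invert_mps(bad), "Hermitian")
})
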