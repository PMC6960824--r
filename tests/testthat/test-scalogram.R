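test_that("zero signal gives an all-zero scalogram", {
  sc <- compute_scalogram(rep(0, 500), sampling_rate = 250)
  expect_true(all(sc$magnitudes == 0))
  expect_true(all(sc$magnitudes >= 0))
})

test_that("scale grid spans the octaves at the requested voice density", {
  sc <- compute_scalogram(rnorm(250), sampling_rate = 250)
  expect_equal(nrow(sc$magnitudes), ceiling(12 * log2(125)))
  expect_equal(nrow(sc$magnitudes), 84)
  expect_true(all(diff(sc$pseudo_frequencies) < 0))
  # Consecutive frequencies differ by exactly one voice step.
  expect_equal(
    sc$pseudo_frequencies[-length(sc$pseudo_frequencies)] /
      sc$pseudo_frequencies[-1],
    rep(2^(1 / 12), 83),
    tolerance = 1e-12
  )
})

test_that("the ridge of a pure tone lands on its pseudo-frequency", {
  fs <- 250
  t <- seq(0, 10, by = 1 / fs)
  voice <- 2^(1 / 12)
  for (f0 in c(5, 10, 20, 40)) {
    sc <- compute_scalogram(sin(2 * pi * f0 * t), sampling_rate = fs)
    ridge <- sc$pseudo_frequencies[which.max(rowMeans(sc$magnitudes))]
    expect_lt(max(ridge / f0, f0 / ridge), voice * 1.0001)
  }
})

test_that("invalid frequency limits are rejected", {
  expect_error(
    compute_scalogram(rnorm(100), freq_limits = c(125, 1), sampling_rate = 250),
    "freq_limits"
  )
  expect_error(
    compute_scalogram(rnorm(100), freq_limits = c(1, 200), sampling_rate = 250),
    "Nyquist"
  )
})

test_that("CWT magnitude is subadditive", {
  set.seed(5)
  x <- rnorm(500)
  y <- rnorm(500)
  mx <- compute_scalogram(x, sampling_rate = 250)$magnitudes
  my <- compute_scalogram(y, sampling_rate = 250)$magnitudes
  mxy <- compute_scalogram(x + y, sampling_rate = 250)$magnitudes
  expect_true(all(mxy <= mx + my + 1e-9))
})

test_that("fall transients localize at the fall episode in the scalogram", {
  # The dominant in-band signature of a simulated fall is the floor impact,
  # which occurs one free-fall time after the onset, so localization is
  # checked against the onset-to-impact episode with a 0.5 s margin.
  ds <- tiny_dataset()
  m <- ds$manifest
  falls <- m[m$label == "fall" & m$radar_id == 1, ]
  for (k in seq_len(nrow(falls))) {
    rec <- ds$records[[falls$record_id[k]]]
    ms <- filter_motion(pca_demodulate(rec))
    sc <- compute_scalogram(ms)
    hi <- sc$pseudo_frequencies > 5
    energy <- colSums(sc$magnitudes[hi, ]^2)
    t_peak <- sc$times[which.max(energy)]
    t0 <- falls$fall_onset_s[k]
    t1 <- t0 + free_fall_duration(1.2) / 0.9 # slowest subject's impact time
    expect_gt(t_peak, t0 - 0.5)
    expect_lt(t_peak, t1 + 0.5)
  }
})

test_that("rendering produces the classifier input contract", {
  sc <- compute_scalogram(sin(2 * pi * 8 * seq(0, 10, by = 1 / 250)),
    sampling_rate = 250
  )
  img <- render_scalogram(sc)
  expect_equal(dim(img), c(227, 227, 3))
  expect_true(all(is.finite(img)))
  expect_true(all(img >= 0 & img <= 1))
})

test_that("degenerate and scaled scalograms render predictably", {
  sc <- compute_scalogram(rep(0, 400), sampling_rate = 250)
  img <- render_scalogram(sc)
  # Uniform image at the jet colormap's lowest entry (dark blue).
  expect_equal(max(abs(img[, , 1])), 0)
  expect_equal(max(abs(img[, , 2])), 0)
  expect_equal(range(img[, , 3]), c(0.5, 0.5))

  set.seed(6)
  sc1 <- compute_scalogram(rnorm(400), sampling_rate = 250)
  sc10 <- sc1
  sc10$magnitudes <- sc10$magnitudes * 10
  # Scale-invariance of min-max normalization (up to floating-point
  # rounding in the rescaled magnitudes).
  expect_equal(
    unclass(render_scalogram(sc1)),
    unclass(render_scalogram(sc10)),
    tolerance = 1e-12
  )
  # Bit-identical rendering for identical input.
  expect_identical(
    unclass(render_scalogram(sc1)),
    unclass(render_scalogram(sc1))
  )
})
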