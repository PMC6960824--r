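# Closed-form 2x2 eigendecomposition used as the independent PCA oracle.
eigen2x2 <- function(S) {
  a <- S[1, 1]
  b <- S[1, 2]
  c <- S[2, 2]
  d <- sqrt((a - c)^2 + 4 * b^2)
  l1 <- (a + c + d) / 2
  v <- if (b != 0) c(l1 - c, b) else if (a >= c) c(1, 0) else c(0, 1)
  list(values = c(l1, (a + c - d) / 2), vector = v / sqrt(sum(v^2)))
}

test_that("single-channel variance passes through unchanged", {
  set.seed(1)
  s <- sin(2 * pi * 3 * seq(0, 1, by = 1 / 250)) + rnorm(251, 0, 0.1)
  ms <- pca_demodulate(make_record(i = s, q = rep(0, length(s))))
  expect_equal(ms$samples, s - mean(s), tolerance = 1e-12)
  expect_equal(mean(ms$samples), 0, tolerance = 1e-12)
  expect_equal(ms$explained_variance_ratio, 1, tolerance = 1e-12)
})

test_that("perfectly correlated channels give sqrt(2) * centred I", {
  set.seed(2)
  s <- cumsum(rnorm(500))
  ms <- pca_demodulate(make_record(i = s, q = s))
  expect_equal(ms$samples, sqrt(2) * (s - mean(s)), tolerance = 1e-9)
  expect_equal(ms$explained_variance_ratio, 1, tolerance = 1e-12)
})

test_that("principal axis matches the closed-form 2x2 eigendecomposition", {
  # Construct a sample cloud with exact covariance [[2,1],[1,2]].
  set.seed(3)
  n <- 400
  Z <- matrix(rnorm(2 * n), n, 2)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(stats::cov(Z))) # exact identity sample covariance
  X <- Z %*% chol(matrix(c(2, 1, 1, 2), 2))
  ms <- pca_demodulate(make_record(i = X[, 1], q = X[, 2]))
  or <- eigen2x2(matrix(c(2, 1, 1, 2), 2))
  expect_equal(or$values, c(3, 1))
  expect_equal(abs(or$vector), rep(1 / sqrt(2), 2))
  expect_equal(stats::var(ms$samples), 3, tolerance = 1e-9)

  # Property: over random clouds, the first-component variance equals the
  # largest closed-form eigenvalue of the sample covariance.
  for (k in 1:20) {
    set.seed(100 + k)
    n <- sample(50:300, 1)
    A <- matrix(rnorm(4), 2, 2)
    X <- matrix(rnorm(2 * n), n, 2) %*% A
    ms <- pca_demodulate(make_record(i = X[, 1], q = X[, 2]))
    l1 <- eigen2x2(stats::cov(X))$values[1]
    expect_equal(stats::var(ms$samples), l1, tolerance = 1e-9)
    # Sign convention: non-negative correlation with the raw I channel.
    expect_gte(sum(ms$samples * (X[, 1] - mean(X[, 1]))), 0)
  }
})

test_that("degenerate constant channels yield a flagged zero signal", {
  expect_warning(
    ms <- pca_demodulate(make_record(i = rep(2, 100), q = rep(-1, 100))),
    "degenerate"
  )
  expect_true(ms$degenerate)
  expect_equal(ms$samples, rep(0, 100))
  expect_error(
    pca_demodulate(make_record(i = 1:10, q = 1:9)),
    "lengths differ"
  )
})

test_that("designed Butterworth response is -3.01 dB at the cut-off", {
  expect_equal(20 * log10(motion_filter_response(5)), -3.0103, tolerance = 0.02)
  expect_equal(
    20 * log10(motion_filter_response(5, mode = "lowpass")),
    -3.0103,
    tolerance = 0.02
  )
})

test_that("high-pass removes DC and passes 20 Hz at unit gain", {
  fs <- 250
  t <- seq(0, 10, by = 1 / fs)
  dc <- filter_motion(rep(3, length(t)), sampling_rate = fs)
  edge <- 100
  core <- seq(edge, length(t) - edge)
  expect_lt(max(abs(dc$samples[core])), 3 * 1e-6)

  x <- sin(2 * pi * 20 * t)
  y <- filter_motion(x, sampling_rate = fs)$samples
  amp <- sqrt(2 * mean(y[core]^2))
  expect_lt(abs(20 * log10(amp)), 0.1)
})

test_that("filtering is linear", {
  set.seed(4)
  fs <- 250
  x <- rnorm(1000)
  y <- rnorm(1000)
  fa <- filter_motion(2 * x - 3 * y, sampling_rate = fs)$samples
  fb <- 2 * filter_motion(x, sampling_rate = fs)$samples -
    3 * filter_motion(y, sampling_rate = fs)$samples
  expect_equal(fa, fb, tolerance = 1e-9)
})

test_that("high-pass separates 20 Hz from 1 Hz by at least 30 dB", {
  fs <- 250
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 1 * t) + sin(2 * pi * 20 * t)
  y <- filter_motion(x, sampling_rate = fs)$samples
  sp <- Mod(stats::fft(y))
  hz_bin <- function(f) round(f * length(t) / fs) + 1
  gain_db <- 20 * log10(sp[hz_bin(20)] / sp[hz_bin(1)])
  expect_gte(gain_db, 30)
})

test_that("cut-off at or above Nyquist is rejected with both values", {
  err <- tryCatch(
    filter_motion(rnorm(100), cutoff_hz = 130, sampling_rate = 250),
    error = conditionMessage
  )
  expect_match(err, "130")
  expect_match(err, "125")
})
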