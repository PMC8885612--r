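cfg <- detector_config()

test_that("bandpass removes DC/gravity and passes the compression band", {
  # all-zero in, all-zero out
  z <- make_trace(rep(0, 2500))
  expect_equal(bandpass(z, cfg)$v, rep(0, 2500))

  # a pure gravity offset is outside the passband
  g <- make_trace(rep(9.81, 5000))
  expect_lt(max(abs(bandpass(g, cfg)$v[1000:4000])), 9.81 * 1e-6)

  # a 2 Hz unit sinusoid passes with the analytic zero-phase gain:
  # |H(f)|^2 of the designed filter, evaluated independently from the
  # transfer-function polynomials
  fs <- 250
  tr <- sine_trace(60, freq = 2, fs = fs)
  filt <- signal::butter(cfg$filter_order,
                         c(cfg$band_low, cfg$band_high) / (fs / 2),
                         type = "pass")
  z1 <- exp(-1i * 2 * pi * 2 / fs)
  gain2 <- Mod(sum(filt$b * z1^(seq_along(filt$b) - 1)) /
                 sum(filt$a * z1^(seq_along(filt$a) - 1)))^2
  out <- bandpass(tr, cfg)
  mid <- out$v[tr$t > 25 & tr$t < 35]
  expect_equal(max(mid), gain2, tolerance = 0.02)

  # band edge above Nyquist is refused
  slow <- make_trace(rnorm(500), fs = 80)
  expect_error(bandpass(slow, cfg), "band edge above Nyquist")
})

test_that("applying the bandpass twice squares the per-tone gain", {
  fs <- 250
  t <- seq(0, 40, by = 1 / fs)
  freqs <- c(0.5, 2, 5, 20)
  v <- rowSums(sapply(freqs, function(f) sin(2 * pi * f * t + f)))
  tr <- tibble::tibble(t = t, v = v)
  once <- bandpass(tr, cfg)
  twice <- bandpass(once, cfg)
  # complex demodulation amplitude estimate over the interior
  amp <- function(x, f) {
    sel <- t > 10 & t < 30
    2 * Mod(mean(x[sel] * exp(-2i * pi * f * t[sel])))
  }
  for (f in freqs) {
    g1 <- amp(once$v, f) / amp(tr$v, f)
    g2 <- amp(twice$v, f) / amp(tr$v, f)
    expect_equal(g2, g1^2, tolerance = 0.02)
  }
})

test_that("the envelope is an exact windowed mean of |v| with truncated edges", {
  # constant |v| gives the same constant everywhere, including edges
  const <- make_trace(rep(c(-3, 3), length.out = 1000))
  expect_equal(sliding_abs_mean(const, cfg)$e, rep(3, 1000))

  # unit 2 Hz sinusoid: interior envelope is the mean of |sin| = 2/pi
  tr <- sine_trace(30, freq = 2)
  e <- sliding_abs_mean(tr, cfg)$e
  interior <- seq(1000, 6000)
  expect_equal(max(abs(e[interior] - 2 / pi)), 0, tolerance = 1e-4)

  # a single impulse of height h contributes h / (window_s * fs)
  v <- rep(0, 2000)
  v[1000] <- 7
  e_imp <- sliding_abs_mean(make_trace(v), cfg)$e
  expect_equal(max(e_imp), 7 / (1 * 250))

  # delaying the input delays the envelope (interior shift-equivariance)
  set.seed(7)
  x <- rnorm(3000)
  k <- 100
  e0 <- sliding_abs_mean(make_trace(x), cfg)$e
  e1 <- sliding_abs_mean(make_trace(c(rep(0, k), x)), cfg)$e
  expect_equal(e1[(500 + k):(2500 + k)], e0[500:2500])

  expect_error(
    sliding_abs_mean(make_trace(rnorm(100)), detector_config(window_s = 1e-3)),
    "shorter than 2 samples"
  )
})

test_that("the smoothed derivative matches closed forms", {
  fs <- 250
  n <- 3000
  tt <- (seq_len(n) - 1) / fs

  # constant envelope -> identically zero
  d0 <- smooth_derivative(tibble::tibble(t = tt, e = rep(2, n)), cfg)
  expect_equal(d0$d, rep(0, n))

  # linear ramp of slope m -> m in the interior
  d1 <- smooth_derivative(tibble::tibble(t = tt, e = 0.3 * tt), cfg)
  expect_equal(d1$d[300:2700], rep(0.3, 2401), tolerance = 1e-9)

  # constant plus ramp recovers the slope to < 1 %
  d1b <- smooth_derivative(tibble::tibble(t = tt, e = 5 + 0.3 * tt), cfg)
  expect_lt(max(abs(d1b$d[300:2700] - 0.3)) / 0.3, 0.01)

  # unit step: interior peak equals 1 / window_s; cross-checked against a
  # brute-force convolution of the difference kernel with the window
  e <- as.numeric(tt >= 6)
  ds <- smooth_derivative(tibble::tibble(t = tt, e = e), cfg)
  expect_equal(max(ds$d), 1 / cfg$window_s, tolerance = 1e-9)
  brute <- sapply(1500:1510, function(i) {
    diffs <- c(e[2] - e[1], (e[3:n] - e[1:(n - 2)]) / 2, e[n] - e[n - 1]) * fs
    w <- (i - 125):(i + 124)
    mean(diffs[w])
  })
  expect_equal(ds$d[1500:1510], brute, tolerance = 1e-12)
})

test_that("soft shrinkage matches its closed form and is a contraction", {
  lam1 <- detector_config(shrink_lambda = 1)
  shrink <- function(x) soft_shrink(tibble::tibble(t = seq_along(x), d = x), lam1)$d
  expect_identical(shrink(c(0.5, 3, -3, 1, -1, 0)), c(0, 2, -2, 0, 0, 0))

  set.seed(11)
  x <- rnorm(500, sd = 2)
  y <- shrink(x)
  expect_true(all(abs(y) <= abs(x)))
  expect_true(all(y[abs(x) <= 1] == 0))
  expect_equal(y, sign(x) * pmax(abs(x) - 1, 0))

  # adaptive threshold: shrink_frac times the 95th percentile of |d|
  d <- tibble::tibble(t = seq_along(x), d = x)
  expect_equal(
    shrink_threshold(d, cfg),
    0.1 * as.numeric(quantile(abs(x), 0.95))
  )
  expect_equal(attr(soft_shrink(d, cfg), "lambda"), shrink_threshold(d, cfg))
})
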