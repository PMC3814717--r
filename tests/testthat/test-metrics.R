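test_that("shifted correlation finds exact matches and delays", {
  set.seed(11)
  a <- as.numeric(stats::filter(rnorm(600), rep(1, 5), sides = 2))
  a[is.na(a)] <- 0
  self <- shifted_correlation(a, a, dt_ms = 1, max_shift_ms = 5)
  expect_equal(self$coefficient, 1)
  expect_equal(self$shift_ms, 0)

  b <- c(rep(0, 3), a[1:597]) # a delayed by 3 ms
  del <- shifted_correlation(a, b, dt_ms = 1, max_shift_ms = 5)
  expect_gt(del$coefficient, 0.99)
  expect_equal(del$shift_ms, 3)

  # symmetry under swapping with shift negation
  sw <- shifted_correlation(b, a, dt_ms = 1, max_shift_ms = 5)
  expect_equal(sw$shift_ms, -del$shift_ms)
  expect_equal(sw$coefficient, del$coefficient, tolerance = 0.02)

  expect_error(shifted_correlation(rep(1, 100), a[1:100], 1, 5), "variance")
})

test_that("white-noise max-shifted correlation matches a permutation null", {
  set.seed(12)
  n <- 400
  a <- rnorm(n); b <- rnorm(n)
  obs <- shifted_correlation(a, b, 1, 5)$coefficient
  # oracle: permutation distribution of the max-shifted coefficient
  null <- replicate(200, shifted_correlation(a, sample(b), 1, 5)$coefficient)
  expect_lt(obs, quantile(null, 0.995))
  expect_gt(obs, quantile(null, 0.005) - 0.05)
  # the max over 11 shifts inflates the coefficient above the single-lag
  # null scale 1/sqrt(n)
  expect_gt(median(null), 1 / sqrt(n))
})

test_that("power spectra locate tones and conserve variance", {
  dt <- 1; fs <- 1000
  t <- seq_len(4096) * dt
  x <- sin(2 * pi * 40 * t / 1000)
  ps <- power_spectrum(x, dt, segment = 1024)
  expect_equal(ps$freq_hz[which.max(ps$power)], 40,
               tolerance = fs / 1024 + 1e-9)
  expect_equal(dominant_frequency(x, dt), 40, tolerance = 0.5)

  # Parseval with a rectangular window and a single segment
  set.seed(13)
  y <- rnorm(2048)
  ps2 <- power_spectrum(y, dt, segment = 2048, window = "rect")
  df <- ps2$freq_hz[2] - ps2$freq_hz[1]
  expect_equal(sum(ps2$power) * df, var(y) * (2047 / 2048), tolerance = 0.01)

  # white noise: no dominant line at 10x the spectral floor
  psw <- power_spectrum(y, dt, segment = 256)
  expect_lt(max(psw$power) / stats::median(psw$power), 10)
  expect_error(power_spectrum(y[1:10], dt, segment = 64), "short")
})

test_that("cross-correlograms report the right lags", {
  set.seed(14)
  a <- as.numeric(stats::filter(rnorm(2000), rep(1, 9), sides = 2))
  a[is.na(a)] <- 0
  cc <- cross_correlogram(a, a, dt_ms = 1, max_lag_ms = 20)
  expect_equal(attr(cc, "peak_lag_ms"), 0)
  expect_equal(max(cc$correlation), 1, tolerance = 1e-6)

  b <- c(rep(0, 4), a[1:1996])
  cc2 <- cross_correlogram(a, b, dt_ms = 1, max_lag_ms = 20)
  expect_equal(attr(cc2, "peak_lag_ms"), 4)

  # antiphase sinusoids: trough at zero lag, peaks at half a period
  t <- seq_len(3000)
  s1 <- sin(2 * pi * t / 50)
  s2 <- -s1
  cc3 <- cross_correlogram(s1, s2, dt_ms = 1, max_lag_ms = 30)
  expect_lt(cc3$correlation[cc3$lag_ms == 0], -0.99)
  expect_gt(cc3$correlation[cc3$lag_ms == 25], 0.99)
})
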