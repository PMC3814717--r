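test_that("classic model integration matches closed-form solutions", {
  # constant input at the fixed point stays put
  out <- integrate_classic(rep(40, 100), lambda = -0.1, r0 = 40, dt = 0.5)
  expect_true(all(abs(out$rate_hz - 40) < 1e-12))

  # step: single exponential approach at the given rate constant
  rinf <- c(rep(10, 100), rep(30, 300))
  out <- integrate_classic(rinf, lambda = -0.05, r0 = 10, dt = 0.5)
  t_post <- (1:300) * 0.5
  expect_equal(out$rate_hz[101:400], 30 - 20 * exp(-0.05 * t_post),
               tolerance = 1e-10)

  # sinusoidal drive: steady-state amplitude follows the low-pass formula
  dt <- 0.05; f <- 20 # Hz
  w <- 2 * pi * f / 1000
  tt <- seq(dt, 4000, by = dt)
  lam <- 0.08
  out <- integrate_classic(50 + 5 * sin(w * tt), -lam, 50, dt)
  amp <- diff(range(out$rate_hz[tt > 2000])) / 2
  expect_equal(amp, 5 * lam / sqrt(lam^2 + w^2), tolerance = 0.01)
})

test_that("the universal eigenvalue map scales and validates", {
  expect_equal(Im(lambda_from_fit(100, 0.2)), 2 * Im(lambda_from_fit(50, 0.2)))
  l <- lambda_from_fit(50, 0.3)
  expect_lt(Re(l), 0); expect_gt(Im(l), 0)
  expect_equal(Im(l), 2 * pi * 0.05)
  expect_equal(Re(l), -2 * pi^2 * 0.09 * 0.05)
  # decay is slowest in the low-noise limit
  expect_gt(Re(lambda_from_fit(50, 0.05)), Re(lambda_from_fit(50, 0.5)))
  expect_error(lambda_from_fit(-1, 0.1), "rate")
  expect_warning(lambda_from_fit(50, 0.9, warn_domain = TRUE), "validity")
})

test_that("complex-model trajectories solve the piecewise-linear ODE", {
  tab <- eif_network_table()
  op <- eif_baseline()
  # constant drive at the fixed point stays put
  cx <- integrate_complex(rep(op$mu, 200), op$sigma, tab, dt = 0.1)
  expect_lt(diff(range(cx$rate_hz)), 1e-6)
  expect_true(all(abs(cx$imag_hz) < 1e-8))

  # step drive: closed-form damped oscillation toward the new fixed point
  mu2 <- op$mu + 1
  lk2 <- table_lookup(tab, mu2, op$sigma)
  lam2 <- lambda_from_fit(lk2$rate_hz, max(lk2$cv, 0.02))
  n <- 2000; dt <- 0.1
  cx2 <- integrate_complex(rep(mu2, n), op$sigma, tab, dt = dt,
                           r0 = op$rate_hz)
  tt <- (1:n) * dt
  closed <- Re(lk2$rate_hz + (op$rate_hz - lk2$rate_hz) * exp(lam2 * tt))
  expect_equal(cx2$rate_hz, closed, tolerance = 1e-8)
  # the transient rings at Im(lambda) and decays at |Re(lambda)|
  ft <- fit_damped_cosine(tt, cx2$rate_hz, blank_ms = 5, window_ms = 150)
  expect_equal(ft$omega, Im(lam2), tolerance = 0.01)
  expect_equal(ft$alpha, Re(lam2), tolerance = 0.01)

  # with the imaginary part forced to zero the model reduces to the classic
  fit0 <- lambda_fit(im_coef = 1e-9)
  cx0 <- integrate_complex(rep(mu2, 500), op$sigma, tab, fit = fit0,
                           dt = dt, r0 = op$rate_hz)
  cl0 <- integrate_classic(rep(lk2$rate_hz, 500), Re(lam2), op$rate_hz, dt)
  expect_equal(cx0$rate_hz, cl0$rate_hz, tolerance = 1e-6)
})

test_that("classic-lambda fitting is self-consistent on synthetic data", {
  p <- neuron_params("eif")
  op <- eif_baseline()
  fit <- fit_classic_lambda(p, op$mu - 1, op$mu, op$sigma, n_neurons = 200,
                            n_reps = 4, seed = 21)
  expect_lt(fit$lambda, 0)
  # rates on either side of the step are recovered
  expect_equal(fit$r_hi_hz, 50, tolerance = 0.1 * 50)
  # degenerate flat input errors out
  expect_error(fit_classic_lambda(p, 2, 2, 1e-9, n_neurons = 5, n_reps = 1),
               "PSTH|ISIs|flat")
})

test_that("the complex-model frequency response peaks at the firing rate", {
  freq <- seq(1, 150, by = 1)
  lr <- complex_linear_response(50, 0.1, dmu_gain = 8.6, freq_hz = freq)
  expect_equal(lr$gain_hz_per_mv[1], 8.6, tolerance = 0.01)
  expect_equal(freq[which.max(lr$gain_hz_per_mv)], 50, tolerance = 1.1)
  # phase lag strictly inside (0, pi)
  expect_true(all(lr$phase_rad > 0 & lr$phase_rad < pi))
})
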