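test_that("stationary solutions satisfy the flux and normalization laws", {
  cases <- list(list("lif", 15, 4), list("lif", 21.5, 1),
                list("eif", 12.6, 0.74), list("qif", 24.7, 5.7))
  for (cs in cases) {
    p <- neuron_params(cs[[1]])
    st <- fp_steady_state(p, cs[[2]], cs[[3]])
    d <- st$density
    dv <- d$v[2] - d$v[1]
    mass <- sum((d$p0[-1] + d$p0[-nrow(d)]) / 2) * dv
    # total probability: density + refractory (and truncated-tail) mass
    expect_equal(mass + st$refractory_mass, 1, tolerance = 1e-3)
    expect_true(all(d$p0 >= 0))
    # absorbing boundary: the density vanishes at threshold
    expect_lt(d$p0[nrow(d)] * dv, 1e-3)
    # flux equals the rate above reset and drops by the rate below it
    expect_equal(max(d$flux_hz), st$rate_hz, tolerance = 1e-10)
    i_reset <- which(d$flux_hz == 0)
    if (length(i_reset) > 0)
      expect_true(all(d$v[i_reset] <= max(p$v_reset, p$v_floor) + 1e-9))
  }
  expect_error(fp_steady_state(neuron_params("lif"), 15, 0), "sigma")
})

test_that("LIF steady-state rate matches the classical Siegert formula", {
  p <- neuron_params("lif")
  for (cs in list(c(15, 4), c(15, 2), c(21.5, 1), c(25, 0.8))) {
    expect_equal(fp_steady_state(p, cs[1], cs[2])$rate_hz,
                 siegert_lif_rate(cs[1], cs[2]), tolerance = 2e-3)
  }
  # deep subthreshold: vanishing escape rate
  expect_lt(fp_steady_state(p, 5, 1.5)$rate_hz, 1e-3)
})

test_that("first-passage and stationary routes agree on the rate", {
  for (m in c("lif", "qif", "eif")) {
    p <- neuron_params(m)
    mu <- c(lif = 21, qif = 25, eif = 12)[[m]]
    rc <- fp_isi_cv(p, mu, 2)
    st <- fp_steady_state(p, mu, 2)
    expect_equal(rc$rate_hz, st$rate_hz, tolerance = 2e-3)
  }
})

test_that("the ISI CV spans the deterministic and Poisson-like limits", {
  p <- neuron_params("lif")
  expect_lt(fp_isi_cv(p, 25, 0.1)$cv, 0.03)        # mean-dominated
  expect_gt(fp_isi_cv(p, 12, 2.5)$cv, 0.85)        # noise-dominated escape
})

test_that("grid refinement is converged at the default spacing", {
  p <- neuron_params("eif")
  op <- eif_baseline()
  r1 <- fp_steady_state(p, op$mu, op$sigma, dv = 2^-4)$rate_hz
  r2 <- fp_steady_state(p, op$mu, op$sigma, dv = 2^-5)$rate_hz
  expect_lt(abs(r1 / r2 - 1), 5e-4)
})

test_that("dominant eigenvalues are stable and conjugate-normalized", {
  for (m in c("lif", "qif", "eif")) {
    p <- neuron_params(m)
    mu <- c(lif = 21.5, qif = 24.7, eif = 12.6)[[m]]
    sg <- c(lif = 1, qif = 5.7, eif = 0.74)[[m]]
    ev <- fp_eigenvalue(p, mu, sg)
    expect_lt(Re(ev$lambda), 0)
    expect_gte(Im(ev$lambda), 0)
  }
})

test_that("EIF eigenvalue converges to the LIF in the sharp-spike limit", {
  lif <- neuron_params("lif")
  ev_lif <- fp_eigenvalue(lif, 21.5, 1)
  # EIF with vanishing spike width and soft threshold at the LIF threshold
  eif0 <- neuron_params("eif", v_t = 20, delta_t = 0.01, v_reset = 10,
                        tau_ref = 0, v_ceiling = 20.15)
  ev_eif <- fp_eigenvalue(eif0, 21.5, 1, guess = ev_lif$lambda, dv = 2^-7)
  expect_lt(Mod(ev_eif$lambda - ev_lif$lambda) / Mod(ev_lif$lambda), 0.05)
})

test_that("QIF eigenvalues come from a converged Fourier truncation", {
  p <- neuron_params("qif")
  e100 <- fp_eigenvalue(p, 24.7, 5.7, n_fourier = 100)
  e200 <- fp_eigenvalue(p, 24.7, 5.7, n_fourier = 200)
  expect_lt(Mod(e100$lambda - e200$lambda) / Mod(e200$lambda), 0.005)
  # the QIF stationary rate from the Fourier route matches the
  # first-passage quadrature
  M <- cvrate:::qif_theta_matrix(p, 24.7, 5.7, 100)
  st <- cvrate:::qif_theta_stationary(M)
  expect_equal(st$rate_hz, fp_isi_cv(p, 24.7, 5.7)$rate_hz, tolerance = 2e-3)
})

test_that("linear response has the quasi-static DC limit", {
  h <- 0.05
  for (m in c("lif", "qif", "eif")) {
    p <- neuron_params(m)
    mu <- c(lif = 21.5, qif = 24.7, eif = 12.6)[[m]]
    sg <- c(lif = 1, qif = 5.7, eif = 0.74)[[m]]
    lr <- fp_linear_response(p, mu, sg, freq_hz = 0.5)
    dmu <- (fp_isi_cv(p, mu + h, sg)$rate_hz -
              fp_isi_cv(p, mu - h, sg)$rate_hz) / (2 * h)
    expect_equal(lr$gain_hz_per_mv, dmu, tolerance = 0.02)
    expect_equal(lr$phase_rad, 0, tolerance = 0.1)
  }
})

test_that("the resonance peak tracks the firing rate and fades with noise", {
  p <- neuron_params("eif")
  op <- eif_baseline()
  freq <- seq(2, 120, by = 2)
  lr <- fp_linear_response(p, op$mu, op$sigma, freq)
  expect_equal(freq[which.max(lr$gain_hz_per_mv)], 50, tolerance = 2.1)
  # high noise: low-pass, no interior peak
  op7 <- calibrate_operating_point(p, 50, 0.7)
  lr7 <- fp_linear_response(p, op7$mu, op7$sigma, freq)
  expect_equal(which.max(lr7$gain_hz_per_mv), 1)
})

test_that("PDE integrator holds a stationary state stationary", {
  p <- neuron_params("eif")
  op <- eif_baseline()
  tr <- fp_pde_transient(p, op$mu, op$mu, op$sigma, duration = 50)
  expect_equal(mean(tr$rate_hz), op$rate_hz, tolerance = 5e-3)
  expect_lt(diff(range(tr$rate_hz[tr$time_ms > 5])), 0.35)
})

test_that("damped-cosine fitting recovers known parameters", {
  t <- seq(0.1, 150, by = 0.1)
  y <- 50 + 8 * exp(-0.02 * (t - 20)) * cos(0.3 * (t - 20) + 1) *
    (t > 20) + 0 * t
  ft <- fit_damped_cosine(t, y, blank_ms = 20, window_ms = 100)
  expect_equal(ft$alpha, -0.02, tolerance = 0.02)
  expect_equal(ft$omega, 0.3, tolerance = 0.01)
})

test_that("operating tables interpolate and invert consistently", {
  tab <- eif_network_table()
  mg <- attr(tab, "mu_grid"); sg <- attr(tab, "sigma_grid")
  # interpolation at grid midpoints vs direct solves within 1%
  p <- neuron_params("eif")
  i_mid <- which.min(abs(mg - 12.6))
  mu_q <- (mg[i_mid] + mg[i_mid + 1]) / 2; sg_q <- (sg[3] + sg[4]) / 2
  lk <- table_lookup(tab, mu_q, sg_q)
  direct <- fp_isi_cv(p, mu_q, sg_q)
  expect_equal(lk$rate_hz, direct$rate_hz, tolerance = 0.01)
  expect_equal(lk$cv, direct$cv, tolerance = 0.05)
  # monotonicity of the rate in mu at fixed sigma (strict once firing)
  rate_mat <- cvrate:::table_field(tab, "rate_hz")
  expect_true(all(apply(rate_mat, 2, function(x) {
    all(diff(x) >= 0) && all(diff(x[x > 0.1]) > 0)
  })))
  # round trip (rate, cv) -> (mu, sigma) at an interior node
  k <- which(tab$rate_hz > 20 & tab$rate_hz < 100 &
               tab$sigma == sg[4])[3]
  inv <- table_invert(tab, tab$rate_hz[k], tab$cv[k])
  expect_equal(unname(inv["mu"]), tab$mu[k], tolerance = 0.01)
  expect_equal(unname(inv["sigma"]), sg[4], tolerance = 0.01 * sg[4])
  # no silent extrapolation
  expect_error(table_lookup(tab, max(mg) + 5, sg[2]), "hull")
})

test_that("operating-point calibration reproduces its targets", {
  op <- eif_baseline()
  p <- neuron_params("eif")
  direct <- fp_isi_cv(p, op$mu, op$sigma)
  expect_equal(direct$rate_hz, 50, tolerance = 5e-3)
  expect_equal(direct$cv, 0.1, tolerance = 5e-3)
  # calibrating to a stored node's values recovers that node
  tab <- eif_network_table()
  sg <- attr(tab, "sigma_grid")
  k <- which(tab$rate_hz > 20 & tab$rate_hz < 100 & tab$sigma == sg[4])[3]
  op2 <- calibrate_operating_point(p, tab$rate_hz[k], tab$cv[k])
  expect_equal(op2$mu, tab$mu[k], tolerance = 0.01)
  expect_equal(op2$sigma, sg[4], tolerance = 0.02 * sg[4])
})

test_that("the decay rate steepens with noise at fixed firing rate", {
  p <- neuron_params("eif")
  re_parts <- vapply(c(0.1, 0.25, 0.4), function(cv) {
    op <- calibrate_operating_point(p, 50, cv)
    Re(fp_eigenvalue(p, op$mu, op$sigma)$lambda)
  }, numeric(1))
  expect_true(all(diff(re_parts) < 0))
})
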