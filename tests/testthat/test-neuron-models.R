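test_that("drift functions have the right fixed points and limits", {
  lif <- neuron_params("lif")
  expect_equal(membrane_drift(lif$e_l, lif, input_mean = 0), 0)

  # far below V_T the EIF drift approaches the leaky drift
  eif <- neuron_params("eif")
  v <- c(-60, -40, -20)
  expect_equal(membrane_drift(v, eif, 0), -(v - eif$e_l), tolerance = 1e-6)

  # QIF drift is a quadratic with two real roots for subthreshold input,
  # none for suprathreshold
  qif <- neuron_params("qif")
  v <- seq(-30, 30, by = 0.5)
  dr_sub <- membrane_drift(v, qif, -5)
  dr_sup <- membrane_drift(v, qif, 5)
  expect_equal(sum(diff(sign(dr_sub)) != 0), 2)
  expect_true(all(dr_sup > 0))

  # EIF drift = leaky drift plus a strictly positive exponential term
  v <- seq(-20, 15, by = 0.5)
  expect_true(all(membrane_drift(v, eif, 0) > -(v - eif$e_l)))

  # suprathreshold drive pushes upward from reset, for every model
  for (m in c("lif", "qif", "eif")) {
    p <- neuron_params(m)
    vr <- max(p$v_reset, p$v_floor)
    expect_gt(membrane_drift(vr, p, 40), 0)
  }
})

test_that("deterministic LIF interspike interval matches the closed form", {
  p <- neuron_params("lif")
  mu <- 25
  # closed-form logarithmic ISI of the leaky integrator
  isi_closed <- p$tau_m * log((mu - p$v_reset) / (mu - p$v_th))
  # oracle: direct quadrature of dt = tau dV / (f(V) + mu)
  isi_quad <- integrate(function(v) p$tau_m / membrane_drift(v, p, mu),
                        p$v_reset, p$v_th, rel.tol = 1e-10)$value
  expect_equal(isi_quad, isi_closed, tolerance = 1e-8)
  # and the simulator reproduces it in the noiseless limit
  ras <- simulate_population(p, input_drive(mu, 1e-12), 1, 2000,
                             dt = 0.01, seed = 1)
  isis <- diff(ras$time_ms[ras$time_ms > 100])
  expect_equal(mean(isis), isi_closed, tolerance = 2e-3)
})

test_that("spike_and_reset is a single-transition step rule", {
  p <- neuron_params("eif")
  v <- seq(p$v_reset - 5, p$v_ceiling + 5, by = 0.1)
  out <- spike_and_reset(v, p)
  expect_equal(sum(diff(out$spiked) != 0), 1)
  expect_false(spike_and_reset(p$v_reset, p)$spiked)
  expect_equal(spike_and_reset(p$v_reset, p)$v_new, p$v_reset)
  top <- spike_and_reset(p$v_ceiling, p)
  expect_true(top$spiked)
  expect_equal(top$v_new, p$v_reset)
})

test_that("parameter validation rejects inconsistent sets", {
  expect_error(neuron_params("lif", v_reset = 25), "v_reset")
  expect_error(neuron_params("lif", tau_m = -1), "tau_m")
  expect_error(neuron_params("eif", delta_t = 0), "delta_t")
  expect_error(neuron_params("lif", tau_ref = -1), "tau_ref")
})

test_that("QIF tail traversal times match direct quadrature", {
  p <- neuron_params("qif")
  mu <- 20
  tt <- tail_times(p, mu)
  up_quad <- integrate(function(v) p$tau_m / membrane_drift(v, p, mu),
                       p$v_ceiling, Inf, rel.tol = 1e-10)$value
  dn_quad <- integrate(function(v) p$tau_m / membrane_drift(v, p, mu),
                       -Inf, -p$v_ceiling, rel.tol = 1e-10)$value
  expect_equal(tt$up, up_quad, tolerance = 1e-6)
  expect_equal(tt$down, dn_quad, tolerance = 1e-6)
})

test_that("parameter sets round-trip through flat JSON", {
  p <- neuron_params("eif", delta_t = 1.5)
  f <- tempfile(fileext = ".json")
  write_neuron_params(p, f)
  p2 <- read_neuron_params(f)
  expect_equal(p2[setdiff(names(p2), NULL)], p[names(p)], tolerance = 1e-12)
  unlink(f)
})
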