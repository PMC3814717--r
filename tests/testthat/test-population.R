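test_that("noiseless subthreshold population never spikes", {
  p <- neuron_params("lif")
  ras <- simulate_population(p, input_drive(15, 1e-12), 10, 500, seed = 1)
  expect_equal(nrow(ras), 0)
})

test_that("rasters respect the refractory period", {
  p <- neuron_params("eif")
  op <- eif_baseline()
  ras <- simulate_population(p, input_drive(op$mu, op$sigma), 50, 2000,
                             seed = 2)
  min_isi <- min(unlist(lapply(split(ras$time_ms, ras$neuron),
                               function(t) diff(sort(t)))))
  expect_gte(min_isi, p$tau_ref)
})

test_that("PSTH estimation is exact on constructed rasters", {
  # one spike per neuron inside a single bin
  df <- tibble::tibble(time_ms = rep(10.4, 20), neuron = 0:19)
  ras <- cvrate:::new_spike_raster(df, n_neurons = 20, duration = 100)
  pr <- estimate_rate(ras, bin_ms = 1)
  expect_equal(pr$rate_hz[pr$time_ms == 10.5], 1000)
  expect_equal(sum(pr$rate_hz), 1000)

  # empty raster: all-zero rate, not an error
  ras0 <- cvrate:::new_spike_raster(df[0, ], n_neurons = 20, duration = 100)
  expect_true(all(estimate_rate(ras0, 1)$rate_hz == 0))

  # smoothing preserves the time-integral
  set.seed(4)
  df2 <- tibble::tibble(time_ms = sort(runif(500, 0, 100)),
                        neuron = sample(0:9, 500, TRUE))
  ras2 <- cvrate:::new_spike_raster(df2, n_neurons = 10, duration = 100)
  raw <- estimate_rate(ras2, 1)
  sm <- estimate_rate(ras2, 1, smooth_ms = 2)
  expect_equal(sum(sm$rate_hz), sum(raw$rate_hz), tolerance = 1e-10)
})

test_that("ISI statistics recover periodic and Poisson limits", {
  # perfectly periodic spiking: CV = 0
  df <- tibble::tibble(time_ms = rep(seq(10, 2000, by = 20), 10),
                       neuron = rep(0:9, each = 100))
  ras <- cvrate:::new_spike_raster(df, n_neurons = 10, duration = 2000)
  st <- isi_statistics(ras, discard_ms = 0)
  expect_equal(st$cv, 0)
  expect_equal(st$rate_hz, 50)

  # Poisson spiking: CV = 1, rate = rho (oracle: exponential ISIs)
  set.seed(7)
  tt <- lapply(0:19, function(i) cumsum(rexp(600, rate = 0.05)))
  df2 <- tibble::tibble(time_ms = unlist(tt),
                        neuron = rep(0:19, each = 600))
  df2 <- df2[df2$time_ms < 8000, ]
  ras2 <- cvrate:::new_spike_raster(df2, n_neurons = 20, duration = 8000)
  st2 <- isi_statistics(ras2, discard_ms = 0)
  se <- isi_se(st2$rate_hz, st2$cv, st2$n_isi)
  expect_lt(abs(st2$cv - 1), 4 * se$cv)
  expect_lt(abs(st2$rate_hz - 50), 4 * se$rate)

  # insufficient data is an error
  expect_error(isi_statistics(ras2[1:20, ], discard_ms = 0), "ISIs")
})

test_that("Monte-Carlo rates and CVs match the Fokker-Planck solvers", {
  # the central cross-validation: empirical (rate, CV) vs first-passage
  # predictions, within 3 standard errors, across models and drive regimes
  cases <- list(list("lif", 21.5, 1.0), list("qif", 24.7, 5.7),
                list("eif", 12.0, 2.0), list("eif", 11.0, 4.0))
  for (cs in cases) {
    p <- neuron_params(cs[[1]])
    fp <- fp_isi_cv(p, cs[[2]], cs[[3]])
    ras <- simulate_population(p, input_drive(cs[[2]], cs[[3]]), 200, 10000,
                               seed = 5)
    st <- isi_statistics(ras)
    se <- isi_se(st$rate_hz, st$cv, st$n_isi)
    expect_lt(abs(st$rate_hz - fp$rate_hz), 3 * se$rate,
              label = sprintf("%s rate deviation", cs[[1]]))
    expect_lt(abs(st$cv - fp$cv), 3 * se$cv,
              label = sprintf("%s cv deviation", cs[[1]]))
  }
})

test_that("halving the time step moves the steady-state rate by < 1%", {
  p <- neuron_params("eif")
  op <- eif_baseline()
  r1 <- isi_statistics(simulate_population(p, input_drive(op$mu, op$sigma),
                                           100, 10000, dt = 0.02, seed = 8))
  r2 <- isi_statistics(simulate_population(p, input_drive(op$mu, op$sigma),
                                           100, 10000, dt = 0.01, seed = 8))
  expect_lt(abs(r1$rate_hz / r2$rate_hz - 1), 0.01)
})
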