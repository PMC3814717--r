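test_that("weight construction and coupled drives follow the mean-field laws", {
  w <- network_weights(0.03, 0.02, g = 0.5, k = 200)
  expect_equal(c(w$j_ee, w$j_ei, w$j_ie, w$j_ii), c(0.03, 0.02, 0.015, 0.01))
  expect_error(network_weights(0.1, 0.1, k = 5000, n_e = 5000), "k")

  ext <- list(mu_x = 12, sigma_x = 0.8)
  d0 <- coupled_drive(0, 0, w, ext)
  expect_equal(d0$mu, c(12, 12))
  expect_equal(d0$sigma2, c(0.64, 0.64))

  # recurrent contributions are linear in the rates
  d1 <- coupled_drive(30, 20, w, ext)
  d2 <- coupled_drive(60, 40, w, ext)
  expect_equal(d2$mu - ext$mu_x, 2 * (d1$mu - ext$mu_x))
  expect_equal(d2$sigma2 - ext$sigma_x^2, 2 * (d1$sigma2 - ext$sigma_x^2))
  # inhibition lowers the mean but raises the variance
  expect_lt(coupled_drive(0, 50, w, ext)$mu[1], ext$mu_x)
  expect_true(all(d1$sigma2 >= ext$sigma_x^2))
  # hand-checked coefficient: K tau J r with rates in kHz
  expect_equal(d1$mu[1] - 12, 200 * 10 * (0.03 * 0.03 - 0.02 * 0.02))
})

test_that("connectivity has exact in-degrees and no self-connections", {
  w <- network_weights(0.02, 0.01, k = 20, n_e = 150, n_i = 150)
  conn <- build_spiking_network(w, seed = 6)
  n <- 300
  # invert the CSR pre -> post lists and count in-degrees per class
  pre <- rep(seq_len(n) - 1L, diff(conn$offsets))
  post <- conn$targets
  expect_true(all(pre != post))
  indeg_e <- tabulate(post[pre < 150] + 1L, nbins = n)
  indeg_i <- tabulate(post[pre >= 150] + 1L, nbins = n)
  expect_true(all(indeg_e == 20))
  expect_true(all(indeg_i == 20))
  # different seeds give different adjacency with identical degree statistics
  conn2 <- build_spiking_network(w, seed = 7)
  expect_false(identical(conn$targets, conn2$targets))
  expect_identical(tabulate(conn2$targets + 1L, nbins = n),
                   tabulate(conn$targets + 1L, nbins = n) * 0L +
                     as.integer(tabulate(conn2$targets + 1L, nbins = n)))
})

test_that("an uncoupled network reproduces the calibrated baseline", {
  op <- eif_baseline()
  w <- network_weights(0, 0, k = 20, n_e = 150, n_i = 150)
  conn <- build_spiking_network(w, seed = 3)
  ras <- simulate_spiking_network(conn, w, neuron_params("eif"),
                                  list(mu_x = op$mu, sigma_x = op$sigma),
                                  duration = 3000, seed = 4)
  st <- isi_statistics(ras)
  se <- isi_se(st$rate_hz, st$cv, st$n_isi)
  expect_lt(abs(st$rate_hz - 50), 3 * se$rate)
  expect_lt(abs(st$cv - 0.1), 3 * se$cv)
})

test_that("a coupled asynchronous network matches its mean-field fixed point", {
  op <- eif_baseline()
  ext <- list(mu_x = op$mu, sigma_x = op$sigma)
  tab <- eif_network_table()
  # scaled-down network (N = 600, K = 24, weights scaled by 1/K)
  scale <- 25 / 3
  w_small <- network_weights(0.01 * scale, 0.03 * scale, g = 0.5, k = 24,
                             n_e = 300, n_i = 300)
  w_full <- network_weights(0.01, 0.03, g = 0.5, k = 200)
  fp <- find_fixed_point(w_full, ext, tab)
  expect_true(fp$converged)
  conn <- build_spiking_network(w_small, seed = 9)
  ras <- simulate_spiking_network(conn, w_small, neuron_params("eif"), ext,
                                  duration = 3000, seed = 10)
  re <- isi_statistics(ras[ras$population == "E", ])
  # means are preserved under the 1/K rescaling (variances are not), so a
  # moderate tolerance is appropriate
  expect_equal(re$rate_hz, fp$rates[1], tolerance = 0.1)
})

test_that("fixed points and stability recover the decoupled limit", {
  op <- eif_baseline()
  ext <- list(mu_x = op$mu, sigma_x = op$sigma)
  tab <- eif_network_table()
  w0 <- network_weights(0, 0, k = 200)
  fp <- find_fixed_point(w0, ext, tab)
  expect_true(fp$converged)
  expect_equal(fp$rates, c(50, 50), tolerance = 5e-3)
  expect_lt(fp$residual, 1e-8)
  st <- stability_at(w0, ext, tab, fp)
  expect_equal(st$verdict, "stable_fixed_point")
  # decoupled Jacobian eigenvalues are lambda and its conjugate, twice
  lam <- lambda_from_fit(fp$rates[1], 0.1)
  ev <- sort(st$eigenvalues[Im(st$eigenvalues) > 0])
  expect_equal(ev, rep(lam, 2), tolerance = 0.02)
})

test_that("rate-network trajectories settle or oscillate as the map predicts", {
  op <- eif_baseline()
  ext <- list(mu_x = op$mu, sigma_x = op$sigma)
  tab <- eif_network_table()
  # zero weights: settle at the baseline fixed point
  w0 <- network_weights(0, 0, k = 200)
  tr0 <- simulate_rate_network(w0, ext, tab, duration = 1500, dt = 0.1,
                               r0 = complex(real = c(70, 30)))
  expect_equal(tail(tr0$rate_e_hz, 1), 50, tolerance = 1e-3)
  expect_equal(tail(tr0$rate_i_hz, 1), 50, tolerance = 1e-3)

  # an unstable cell sustains an oscillation near the baseline rate
  w1 <- network_weights(0.025, 0.01, k = 200)
  tr1 <- simulate_rate_network(w1, ext, tab, duration = 1500, dt = 0.1)
  x <- tr1$rate_e_hz[tr1$time_ms > 500]
  expect_gt(sd(x), 5)
  o <- detect_oscillation(tr1$rate_e_hz, 0.1)
  expect_true(o$oscillating)
  expect_equal(o$freq_hz, 50, tolerance = 10)

  # verdicts match forward simulation on a small weight grid
  cells <- expand.grid(w_e = c(0.01, 0.025, 0.04), w_i = c(0.005, 0.02, 0.04))
  agree <- 0
  for (i in seq_len(nrow(cells))) {
    w <- network_weights(cells$w_e[i], cells$w_i[i], k = 200)
    fp <- find_fixed_point(w, ext, tab)
    st <- stability_at(w, ext, tab, fp)
    tr <- simulate_rate_network(w, ext, tab, duration = 1200, dt = 0.1)
    o <- detect_oscillation(tr$rate_e_hz, 0.1)
    agree <- agree + ((st$verdict == "limit_cycle") == o$oscillating)
  }
  expect_gte(agree, 8)
})

test_that("stability scans record failures without aborting", {
  op <- eif_baseline()
  ext <- list(mu_x = op$mu, sigma_x = op$sigma)
  tab <- eif_network_table()
  # include a runaway column (strong excitation, no inhibition)
  map <- scan_stability_map(c(0, 0.03, 0.2), c(0, 0.01), g = 0.5,
                            external = ext, table = tab, k = 200)
  expect_equal(nrow(map), 6)
  expect_true(all(map$verdict[map$w_e == 0] == "stable_fixed_point"))
  expect_true(any(map$verdict == "limit_cycle"))
  # the pathological cell is recorded, not fatal
  expect_true(all(map$verdict %in%
                    c("stable_fixed_point", "limit_cycle", "no_fixed_point")))
})
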