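# Shared fixtures, computed lazily and cached for the whole test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

eif_baseline <- function() {
  cached("eif_baseline",
         calibrate_operating_point(neuron_params("eif"), 50, 0.1, tol = 1e-5))
}

eif_network_table <- function() {
  cached("eif_network_table", {
    op <- eif_baseline()
    network_operating_table(neuron_params("eif"), op, k = 200, w_max = 0.05)
  })
}

# classical Siegert mean-first-passage rate for the LIF (independent
# oracle); the integrand exp(u^2) erfc(-u) is evaluated in scaled form
siegert_lif_rate <- function(mu, sigma, v_th = 20, v_reset = 10, tau = 10) {
  g <- integrate(function(u) pracma::erfcx(-u),
                 (v_reset - mu) / sigma, (v_th - mu) / sigma,
                 rel.tol = 1e-10)
  1000 / (tau * sqrt(pi) * g$value)
}

# pooled-ISI standard errors for rate and CV estimates
isi_se <- function(rate_hz, cv, n_isi) {
  list(rate = rate_hz * cv / sqrt(n_isi),
       cv = cv * sqrt((1 + 2 * cv^2) / (2 * n_isi)))
}

default_stability_map <- function() {
  cached("stability_map_default", {
    op <- eif_baseline()
    scan_stability_map(seq(0, 0.05, by = 0.005), seq(0, 0.05, by = 0.005),
                       g = 0.5,
                       external = list(mu_x = op$mu, sigma_x = op$sigma),
                       table = eif_network_table(), k = 200)
  })
}
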