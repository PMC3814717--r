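# Experiment recipes tying the modules together at configurable scale, with
# deterministic seed fan-out and a JSON manifest per run.

#' Run a named experiment recipe
#'
#' Executes one of the canned study recipes and writes its outputs (CSV) and
#' a JSON manifest (config, seeds, versions) to `out_dir`. Recipes:
#' * `"step_response"`: uncoupled population step response vs both rate
#'   models.
#' * `"lambda_surfaces"`: eigenvalue tabulation over an operating grid.
#' * `"correlation_sweep"`: five-sinusoid protocol, shifted correlation of
#'   complex and classic models against a spiking population, across CV
#'   baselines.
#' * `"linear_response"`: spiking vs complex-model gain/phase curves.
#' * `"stability_map"`: rate-network phase diagram over (w_E, w_I).
#'
#' All stochastic steps derive their seeds from `config$seed` by fixed
#' offsets, so a config reruns identically.
#'
#' @param config list with at least `experiment` and `seed`; recipe-specific
#'   fields documented in the vignette, all with defaults.
#' @param out_dir output directory.
#' @returns (invisibly) a list of output paths (the manifest).
#' @export
run_experiment <- function(config, out_dir = tempfile("cvrate_run_")) {
  if (is.null(config$experiment))
    abort("config must name an `experiment`")
  recipes <- c("step_response", "lambda_surfaces", "correlation_sweep",
               "linear_response", "stability_map")
  if (!config$experiment %in% recipes)
    abort(sprintf("unknown experiment '%s' (known: %s)", config$experiment,
                  paste(recipes, collapse = ", ")))
  config$seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- switch(config$experiment,
    step_response = recipe_step_response(config, out_dir),
    lambda_surfaces = recipe_lambda_surfaces(config, out_dir),
    correlation_sweep = recipe_correlation_sweep(config, out_dir),
    linear_response = recipe_linear_response(config, out_dir),
    stability_map = recipe_stability_map(config, out_dir))
  manifest <- list(experiment = config$experiment, seed = config$seed,
                   config = config, outputs = paths,
                   package_version = as.character(utils::packageVersion("cvrate")))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, manifest = mf))
}

write_csv_ <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

recipe_step_response <- function(cfg, out_dir) {
  p <- neuron_params(cfg$model %||% "eif")
  rate <- cfg$rate_hz %||% 50
  cvs <- cfg$cv %||% 0.1
  n <- cfg$n_neurons %||% 2000
  op <- calibrate_operating_point(p, rate, cvs)
  mu_lo <- op$mu - (cfg$step_mv %||% 1)
  spec <- stimulus_spec("step", baseline = mu_lo, amplitude = op$mu - mu_lo,
                        onset = 200, duration = 500,
                        dt = if (p$model == "lif") 0.05 else 0.02)
  stim <- render_common_input(spec)
  ras <- simulate_population(p, input_drive(stim$i0_mv, op$sigma), n, 500,
                             dt = spec$dt, seed = cfg$seed)
  pr <- estimate_rate(ras, bin_ms = 1, smooth_ms = 2)
  # rate-model twins on the same drive
  tab <- build_operating_table(p, seq(mu_lo - 2, op$mu + 2, length.out = 9),
                               op$sigma * c(0.8, 1, 1.2),
                               with_lambda = FALSE)
  mu_t <- approx(stim$time_ms, stim$i0_mv, pr$time_ms, rule = 2)$y
  cx <- integrate_complex(mu_t, op$sigma, tab, dt = 1)
  lam_c <- fit_classic_lambda(p, mu_lo, op$mu, op$sigma,
                              n_neurons = min(n, 400), n_reps = 5,
                              seed = cfg$seed + 1)
  cl <- integrate_classic(table_lookup(tab, mu_t, rep(op$sigma, length(mu_t)))$rate_hz,
                          lam_c$lambda, cx$rate_hz[1], dt = 1)
  out <- tibble(time_ms = pr$time_ms, spiking_hz = pr$rate_hz,
                complex_hz = cx$rate_hz, classic_hz = cl$rate_hz)
  list(rates = write_csv_(out, file.path(out_dir, "step_response.csv")))
}

recipe_lambda_surfaces <- function(cfg, out_dir) {
  p <- neuron_params(cfg$model %||% "eif")
  mu <- cfg$mu_grid %||% seq(8, 16, by = 2)
  sg <- cfg$sigma_grid %||% c(0.5, 1, 2, 4)
  tab <- build_operating_table(p, mu, sg, with_lambda = TRUE)
  list(table = write_csv_(as_tibble(tab),
                          file.path(out_dir, "lambda_surface.csv")))
}

recipe_correlation_sweep <- function(cfg, out_dir) {
  p <- neuron_params(cfg$model %||% "eif")
  rate <- cfg$rate_hz %||% 50
  cvs <- cfg$cv_values %||% c(0.1, 0.3, 0.5, 0.8)
  res <- purrr::map_dfr(cvs, function(cv) {
    cmp <- compare_rate_models(p, rate, cv, amplitude = cfg$amplitude %||% 1,
                               n_neurons = cfg$n_neurons %||% 1000,
                               duration = cfg$duration %||% 5000,
                               seed = cfg$seed)
    mutate(cmp, cv_target = cv)
  })
  list(correlations = write_csv_(res,
                                 file.path(out_dir, "correlation_sweep.csv")))
}

recipe_linear_response <- function(cfg, out_dir) {
  p <- neuron_params(cfg$model %||% "eif")
  op <- calibrate_operating_point(p, cfg$rate_hz %||% 50, cfg$cv %||% 0.1)
  freq <- cfg$freq_hz %||% seq(1, 200, by = 1)
  sp <- fp_linear_response(p, op$mu, op$sigma, freq)
  h <- 0.05
  dmu <- (fp_rate_cv(p, op$mu + h, op$sigma)$rate_hz -
            fp_rate_cv(p, op$mu - h, op$sigma)$rate_hz) / (2 * h)
  cx <- complex_linear_response(op$rate_hz, op$cv, dmu, freq)
  out <- tibble(freq_hz = freq,
                spiking_gain = sp$gain_hz_per_mv,
                spiking_phase = sp$phase_rad,
                complex_gain = cx$gain_hz_per_mv,
                complex_phase = cx$phase_rad)
  list(linear_response = write_csv_(out,
                                    file.path(out_dir, "linear_response.csv")))
}

recipe_stability_map <- function(cfg, out_dir) {
  p <- neuron_params(cfg$model %||% "eif")
  op <- calibrate_operating_point(p, cfg$rate_hz %||% 50, cfg$cv %||% 0.1)
  external <- list(mu_x = op$mu, sigma_x = op$sigma)
  tab <- network_operating_table(p, op, k = cfg$k %||% 200,
                                 w_max = cfg$w_max %||% 0.06)
  map <- scan_stability_map(
    cfg$w_e_grid %||% seq(0, 0.06, by = 0.01),
    cfg$w_i_grid %||% seq(0, 0.06, by = 0.01),
    g = cfg$g %||% 0.5, external = external, table = tab,
    k = cfg$k %||% 200, n_e = cfg$n_e %||% 5000, n_i = cfg$n_i %||% 5000)
  list(map = write_csv_(as_tibble(map), file.path(out_dir, "stability_map.csv")))
}

#' Operating table sized for a network weight scan
#'
#' Builds an operating table whose (mu, sigma) hull covers the drives the
#' rate network can visit during a scan up to weight scale `w_max`
#' (rates up to `rate_cap_hz`).
#'
#' @param params a [neuron_params()] object.
#' @param op calibrated baseline (tibble with `mu`, `sigma`).
#' @param k in-degree.
#' @param w_max largest scanned weight (mV).
#' @param rate_cap_hz largest population rate the table must cover.
#' @param n_mu,n_sigma grid resolution.
#' @param tau_m membrane time constant (ms).
#' @returns an `operating_table`.
#' @export
network_operating_table <- function(params, op, k = 200, w_max = 0.06,
                                    rate_cap_hz = 450, n_mu = 41,
                                    n_sigma = 10, tau_m = 10) {
  span <- k * tau_m * w_max * rate_cap_hz / 1000
  mu_grid <- seq(op$mu - span, op$mu + span, length.out = n_mu)
  s2_span <- k * tau_m * w_max^2 * (1 + 0.5^2) * rate_cap_hz / 1000
  sigma_grid <- seq(max(op$sigma * 0.5, 0.2),
                    sqrt(op$sigma^2 + s2_span) * 1.05,
                    length.out = n_sigma)
  build_operating_table(params, mu_grid, sigma_grid, with_lambda = FALSE)
}

#' Compare both rate models against a spiking population on the
#' five-sinusoid protocol
#'
#' Calibrates the operating point to `(rate_hz, cv)`, builds the
#' sum-of-sinusoids common input (61, 50, 33, 13.1, 7.9 Hz, random phases),
#' simulates an uncoupled population, integrates the complex-valued model
#' and the CV-matched optimal classic model on the same drive, and scores
#' both with the shifted correlation coefficient against the population
#' PSTH.
#'
#' @param params a [neuron_params()] object.
#' @param rate_hz,cv baseline operating point.
#' @param amplitude per-sinusoid amplitude (mV).
#' @param n_neurons population size.
#' @param duration protocol duration (ms).
#' @param seed integer seed.
#' @param max_shift_ms shift window for the correlation.
#' @param bin_ms,smooth_ms PSTH parameters.
#' @returns tibble with one row per model (`complex`, `classic`) and the
#'   shifted-correlation results.
#' @export
compare_rate_models <- function(params, rate_hz, cv, amplitude = 1,
                                n_neurons = 1000, duration = 5000, seed = 1L,
                                max_shift_ms = 5, bin_ms = 1, smooth_ms = 2) {
  op <- calibrate_operating_point(params, rate_hz, cv)
  sim_dt <- if (params$model == "lif") 0.05 else 0.02
  spec <- stimulus_spec("sinusoid_mix", baseline = op$mu,
                        amplitude = amplitude, duration = duration,
                        dt = sim_dt, seed = seed)
  stim <- render_common_input(spec)
  ras <- simulate_population(params, input_drive(stim$i0_mv, op$sigma),
                             n_neurons, duration, dt = sim_dt, seed = seed + 1)
  pr <- estimate_rate(ras, bin_ms = bin_ms, smooth_ms = smooth_ms)
  # operating table wide enough for the stimulus excursions
  n_sin <- length(spec$frequencies)
  mu_lo <- op$mu - n_sin * amplitude - 0.5
  mu_hi <- op$mu + n_sin * amplitude + 0.5
  tab <- build_operating_table(params,
                               seq(mu_lo, mu_hi, length.out = 13),
                               op$sigma * c(0.9, 1, 1.1),
                               with_lambda = FALSE)
  rate_dt <- 0.1
  n_rate <- round(duration / rate_dt)
  mu_t <- approx(stim$time_ms, stim$i0_mv, (seq_len(n_rate) - 1) * rate_dt,
                 rule = 2)$y
  cx <- integrate_complex(mu_t, op$sigma, tab, dt = rate_dt)
  lam_c <- fit_classic_lambda(params, op$mu - 1, op$mu, op$sigma,
                              n_neurons = 400, n_reps = 10, seed = seed + 2)
  rinf_t <- table_lookup(tab, mu_t, rep(op$sigma, n_rate))$rate_hz
  cl <- integrate_classic(rinf_t, lam_c$lambda, rinf_t[1], dt = rate_dt)
  # common 1 ms comparison grid, discarding a transient
  keep <- pr$time_ms > 300
  grid_t <- pr$time_ms[keep]
  cx_g <- approx(cx$time_ms, cx$rate_hz, grid_t, rule = 2)$y
  cl_g <- approx(cl$time_ms, cl$rate_hz, grid_t, rule = 2)$y
  bind_rows(
    mutate(shifted_correlation(pr$rate_hz[keep], cx_g, bin_ms, max_shift_ms),
           model = "complex"),
    mutate(shifted_correlation(pr$rate_hz[keep], cl_g, bin_ms, max_shift_ms),
           model = "classic")) %>%
    mutate(classic_lambda = lam_c$lambda, mu = op$mu, sigma = op$sigma)
}
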