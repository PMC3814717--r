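# Firing-rate models: the classic single-time-constant model and the
# complex-valued model closed by the universal lambda(r_inf, CV) map.
#
# Sign convention: lambda is stored with Re(lambda) < 0 and the rate ODE is
#   d rhat / dt = lambda * (rhat - r_inf),
# so trajectories relax toward r_inf while oscillating at Im(lambda).

#' Universal lambda(r_inf, CV) parameterization
#'
#' The dominant nonzero Fokker-Planck eigenvalue of the integrate-and-fire
#' models collapses, when expressed as a function of the output statistics,
#' onto an approximately model-independent map
#' \deqn{\lambda = 2\pi r_\infty \left(-\,a\,CV^2 + i\,b\right),}
#' with \eqn{r_\infty} in kHz. The default constants are \eqn{a = \pi}
#' (quadratic low-noise decay of partial spike synchronization, the
#' Gaussian-ISI renewal limit) and \eqn{b = 1} (transient oscillation
#' frequency equal to the steady-state firing rate). The fit targets
#' CV values up to about 0.75; outside that range the decay grows faster
#' than quadratically and the map underestimates it.
#'
#' @param re_coef quadratic CV coefficient \eqn{a} of the real part.
#' @param im_coef linear coefficient \eqn{b} of the imaginary part.
#' @param cv_max upper edge of the validity domain.
#' @returns an object of class `lambda_fit`.
#' @export
lambda_fit <- function(re_coef = pi, im_coef = 1, cv_max = 0.75) {
  stopifnot(re_coef > 0, im_coef > 0)
  structure(list(re_coef = re_coef, im_coef = im_coef, cv_max = cv_max),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf(
    "<lambda_fit: lambda = 2*pi*r_inf*(-%.4f*CV^2 + %.4f i), CV <= %.2f>\n",
    x$re_coef, x$im_coef, x$cv_max))
  invisible(x)
}

#' @method tidy lambda_fit
#' @export
tidy.lambda_fit <- function(x, ...) {
  tibble(term = c("re_coef", "im_coef"),
         estimate = c(x$re_coef, x$im_coef))
}

#' Evaluate the universal eigenvalue map
#'
#' @param rate_hz steady-state rate(s), Hz; must be positive.
#' @param cv ISI coefficient(s) of variation.
#' @param fit a [lambda_fit()]; defaults to the package constants.
#' @param warn_domain warn when `cv` exceeds the fit's validity domain.
#' @returns complex vector, 1/ms, with `Re < 0`, `Im > 0`.
#' @export
lambda_from_fit <- function(rate_hz, cv, fit = lambda_fit(),
                            warn_domain = FALSE) {
  if (any(rate_hz <= 0)) abort("`rate_hz` must be positive")
  if (warn_domain && any(cv > fit$cv_max))
    warn(sprintf("CV above the fit validity domain (%.2f)", fit$cv_max))
  r_khz <- rate_hz / 1000
  complex(real = -2 * pi * fit$re_coef * cv^2 * r_khz,
          imaginary = 2 * pi * fit$im_coef * r_khz)
}

#' Integrate the classic rate model
#'
#' Solves \eqn{dr/dt = \lambda (r - r_\infty(t))} with real negative
#' \eqn{\lambda} by the exact exponential update on each step (the input is
#' treated as constant within a step).
#'
#' @param rinf_hz time series of the instantaneous steady-state rate (Hz).
#' @param lambda real decay rate, 1/ms, negative.
#' @param r0 initial rate (Hz).
#' @param dt step of the `rinf_hz` grid (ms).
#' @returns tibble with `time_ms`, `rate_hz`.
#' @export
integrate_classic <- function(rinf_hz, lambda, r0, dt) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda < 0)
  n <- length(rinf_hz)
  out <- numeric(n)
  e <- exp(lambda * dt)
  r <- r0
  for (k in seq_len(n)) {
    r <- rinf_hz[k] + (r - rinf_hz[k]) * e
    out[k] <- r
  }
  tibble(time_ms = seq_len(n) * dt, rate_hz = out)
}

#' Fit the classic-model decay rate to a population step response
#'
#' Reproduces the calibration procedure for the classic rate model: simulate
#' a population receiving a step of the common input from `mu_lo` to
#' `mu_hi`, average repetitions, and find the real decay rate whose analytic
#' exponential step response best matches the PSTH in the least-squares
#' sense.
#'
#' @param params a [neuron_params()] object.
#' @param mu_lo,mu_hi pre/post-step mean input (mV).
#' @param sigma noise amplitude (mV), constant.
#' @param n_neurons population size per repetition.
#' @param n_reps repetitions averaged.
#' @param t_pre,t_post time before/after the step (ms).
#' @param bin_ms PSTH bin (ms).
#' @param dt integration step (ms).
#' @param seed integer seed.
#' @returns tibble with `lambda` (1/ms, negative), `tau_ms`, `r_lo_hz`,
#'   `r_hi_hz`.
#' @export
fit_classic_lambda <- function(params, mu_lo, mu_hi, sigma, n_neurons = 400,
                               n_reps = 25, t_pre = 300, t_post = 200,
                               bin_ms = 1, dt = NULL, seed = 1L) {
  duration <- t_pre + t_post
  spec <- stimulus_spec("step", baseline = mu_lo, amplitude = mu_hi - mu_lo,
                        onset = t_pre, duration = duration,
                        dt = dt %||% if (params$model == "lif") 0.05 else 0.02)
  stim <- render_common_input(spec)
  psth <- 0
  for (rep in seq_len(n_reps)) {
    ras <- simulate_population(params, input_drive(stim$i0_mv, sigma),
                               n_neurons, duration, dt = spec$dt,
                               seed = seed + 7919 * rep)
    pr <- estimate_rate(ras, bin_ms = bin_ms)
    psth <- psth + pr$rate_hz / n_reps
  }
  tt <- (seq_along(psth) - 0.5) * bin_ms
  post <- tt > t_pre
  t_rel <- tt[post] - t_pre
  y <- psth[post]
  r_lo <- mean(psth[tt > t_pre * 0.5 & tt <= t_pre])
  if (sd(psth) < 1e-9) abort("degenerate (flat) PSTH; no step response to fit")
  sse <- function(lam_abs) {
    # model y = r_hi + (r_lo - r_hi) e; profile the asymptote analytically:
    # least squares in r_hi given lambda reads y - r_lo e = r_hi (1 - e)
    e <- exp(-lam_abs * t_rel)
    w <- 1 - e
    r_hi <- sum(w * (y - r_lo * e)) / sum(w^2)
    sum((y - (r_hi + (r_lo - r_hi) * e))^2)
  }
  opt <- optimize(sse, c(1e-4, 5))
  lam_abs <- opt$minimum
  e <- exp(-lam_abs * t_rel); w <- 1 - e
  r_hi <- sum(w * (y - r_lo * e)) / sum(w^2)
  tibble(lambda = -lam_abs, tau_ms = 1 / lam_abs,
         r_lo_hz = r_lo, r_hi_hz = r_hi)
}

#' Integrate the complex-valued rate model
#'
#' Advances \eqn{d\hat r/dt = \lambda(t)\,(\hat r - r_\infty(t))} with the
#' quasi-static closure: at every step the instantaneous drive
#' \eqn{(\mu(t), \sigma(t))} is mapped through the operating table to
#' \eqn{(r_\infty, CV)}, \eqn{\lambda} is evaluated from the universal fit,
#' and the linear ODE is advanced exactly over the step. The predicted
#' population rate is the real part of \eqn{\hat r}; it may transiently be
#' negative and is reported as-is.
#'
#' @param mu_mv,sigma_mv drive trajectories on the step grid (vectors or
#'   scalars), mV.
#' @param table an `operating_table` for the spiking model being reduced.
#' @param fit a [lambda_fit()].
#' @param dt step (ms).
#' @param r0 initial complex rate (Hz); default: the fixed point of the
#'   initial drive.
#' @param cv_floor lower clip for the CV entering the fit (avoids a
#'   divergent decay time at numerically zero CV).
#' @returns a `complex_rate_state`: tibble with `time_ms`, `rate_hz`
#'   (real part), `imag_hz`.
#' @export
integrate_complex <- function(mu_mv, sigma_mv, table, fit = lambda_fit(),
                              dt = 0.1, r0 = NULL, cv_floor = 0.02) {
  n <- max(length(mu_mv), length(sigma_mv))
  mu_mv <- rep_len(mu_mv, n); sigma_mv <- rep_len(sigma_mv, n)
  lk <- table_lookup(table, mu_mv, sigma_mv) # vectorized, hull-checked
  lam <- lambda_from_fit(pmax(lk$rate_hz, 1e-3), pmax(lk$cv, cv_floor), fit)
  rinf <- lk$rate_hz
  if (is.null(r0)) r0 <- rinf[1]
  r <- as.complex(r0)
  e <- exp(lam * dt)
  out <- complex(n)
  for (k in seq_len(n)) {
    r <- rinf[k] + (r - rinf[k]) * e[k]
    out[k] <- r
  }
  structure(tibble(time_ms = seq_len(n) * dt, rate_hz = Re(out),
                   imag_hz = Im(out)),
            class = c("complex_rate_state", class(tibble())), dt = dt)
}

#' Linear response of the complex-valued rate model
#'
#' For a sinusoidal perturbation of the mean input at angular frequency
#' \eqn{\omega}, the first-order response of the real part of
#' \eqn{\hat r} is \eqn{\epsilon\, r_\infty'\,|G(\omega)|
#' \cos(\omega t - \varphi)} with
#' \deqn{G(\omega) = \tfrac12\left[\frac{\lambda}{\lambda - i\omega} +
#'   \frac{\lambda^*}{\lambda^* - i\omega}\right],}
#' obtained by splitting the complex rate into real and imaginary parts and
#' solving the driven linear system. The DC limit is \eqn{G(0) = 1}, so the
#' zero-frequency gain equals \eqn{dr_\infty/d\mu}.
#'
#' @param rate_hz,cv operating point (steady rate and CV).
#' @param dmu_gain quasi-static gain \eqn{dr_\infty/d\mu} (Hz per mV),
#'   finite-differenced from an operating table or a steady-state solver.
#' @param freq_hz frequency grid (Hz).
#' @param fit a [lambda_fit()].
#' @returns tibble with `freq_hz`, `gain_hz_per_mv`, `phase_rad` (lag,
#'   unwrapped, positive = response lags the stimulus).
#' @export
complex_linear_response <- function(rate_hz, cv, dmu_gain, freq_hz,
                                    fit = lambda_fit()) {
  lam <- lambda_from_fit(rate_hz, cv, fit)
  w <- 2 * pi * freq_hz / 1000
  G <- 0.5 * (lam / (lam - 1i * w) + Conj(lam) / (Conj(lam) - 1i * w))
  tibble(freq_hz = freq_hz,
         gain_hz_per_mv = dmu_gain * Mod(G),
         phase_rad = unwrap_phase(-Arg(G)))
}
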