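# Fokker-Planck solvers for the membrane-potential density of
# integrate-and-fire populations driven by white noise:
#   * stationary density / steady-state rate (threshold integration),
#   * ISI CV from first-passage-time moments,
#   * dominant nonzero eigenvalue lambda_1 (complex threshold integration
#     with Newton-Raphson for LIF/EIF; Fourier expansion of the theta-model
#     for the QIF),
#   * linear response (gain and phase) of the spiking models,
#   * a method-of-lines PDE transient integrator used as an independent
#     oracle for the spectral results.
#
# Internal units: mV, ms; lambda in 1/ms; rates converted to Hz at the API.

# ---- voltage grids ---------------------------------------------------------

# Build the solver grid for one operating point. Anchored at v_reset so that
# the reset potential falls exactly on a node.
fp_grid <- function(params, mu, sigma, dv = 2^-4) {
  top <- min(params$v_th, params$v_ceiling)
  if (params$model == "qif") {
    lo <- -params$v_ceiling
    v <- seq(lo, top, by = dv)
    if (v[length(v)] < top) v <- c(v, v[length(v)] + dv)
    ir <- 1L
  } else {
    rest <- min(mu, top)
    lo <- min(params$v_reset, params$e_l, rest) - max(8 * sigma, 5)
    n_up <- ceiling((top - params$v_reset) / dv)
    n_dn <- ceiling((params$v_reset - lo) / dv)
    v <- params$v_reset + dv * seq(-n_dn, n_up)
    ir <- n_dn + 1L
  }
  list(v = v, i_reset = ir, dv = dv,
       h = membrane_drift(v, params, mu) / params$tau_m,
       D = sigma^2 / (2 * params$tau_m),
       p_top = if (params$model == "lif") 0 else
         params$tau_m / membrane_drift(v[length(v)], params, mu))
}

qif_tail_total <- function(params, mu) {
  tt <- tail_times(params, mu)
  tt$up + tt$down
}

# ---- stationary problem ----------------------------------------------------

#' Stationary membrane-potential density and steady-state rate
#'
#' Threshold integration of the stationary Fokker-Planck equation: the
#' flux/density pair is integrated downward from the absorbing boundary, a
#' flux discontinuity equal to the firing rate is inserted at the reset
#' potential, and the density is normalized including the probability mass
#' held in the refractory state (`r_inf * tau_ref`).
#'
#' @param params a [neuron_params()] object.
#' @param mu mean input (mV).
#' @param sigma input noise amplitude (mV); must be positive (diffusion
#'   approximation).
#' @param dv voltage grid spacing (mV).
#' @returns an `fp_stationary` object: list with `density` (tibble `v`,
#'   `p0` in 1/mV, `flux_hz`), `rate_hz`, `mu`, `sigma`.
#' @export
fp_steady_state <- function(params, mu, sigma, dv = 2^-4) {
  stopifnot(inherits(params, "neuron_params"))
  if (sigma <= 0)
    abort("sigma must be positive; use the deterministic closed form for sigma = 0")
  g <- fp_grid(params, mu, sigma, dv)
  out <- fp_steady_cpp(g$v, g$h, g$D, g$i_reset - 1L, params$tau_ref, g$p_top)
  tail_ms <- if (params$model == "qif") qif_tail_total(params, mu) else 0
  r_khz <- 1 / (out$mass + tail_ms + params$tau_ref)
  structure(
    list(density = tibble(v = g$v, p0 = r_khz * out$p,
                          flux_hz = 1000 * r_khz * out$j),
         rate_hz = 1000 * r_khz, mu = mu, sigma = sigma, params = params,
         refractory_mass = r_khz * (params$tau_ref + tail_ms)),
    class = "fp_stationary")
}

#' @export
print.fp_stationary <- function(x, ...) {
  cat(sprintf("<fp_stationary %s: mu = %.3f, sigma = %.3f, r_inf = %.3f Hz>\n",
              toupper(x$params$model), x$mu, x$sigma, x$rate_hz))
  invisible(x)
}

# rate and CV from the first two first-passage-time moments (internal,
# shared by fp_isi_cv / calibration / tables)
fp_rate_cv <- function(params, mu, sigma, dv = 2^-4) {
  if (sigma <= 0) abort("sigma must be positive")
  g <- fp_grid(params, mu, sigma, dv)
  mom <- fpt_moments_cpp(g$v, g$h, g$D)
  t1 <- mom$t1[g$i_reset]
  t2 <- mom$t2[g$i_reset]
  if (params$model == "qif") {
    shift <- qif_tail_total(params, mu)
    t2 <- t2 + 2 * shift * t1 + shift^2
    t1 <- t1 + shift
  }
  if (!is.finite(t1) || !is.finite(t2)) {
    # escape time beyond double range: vanishing rate, Poisson-like escape
    return(list(rate_hz = 0, cv = 1, t1 = Inf, var = Inf))
  }
  isi <- t1 + params$tau_ref
  vv <- max(t2 - t1^2, 0)
  list(rate_hz = 1000 / isi, cv = sqrt(vv) / isi, t1 = t1, var = vv)
}

#' ISI coefficient of variation from first-passage moments
#'
#' Computes the interspike-interval CV of a white-noise-driven
#' integrate-and-fire neuron from the first two moments of the first-passage
#' time from reset to threshold (stable exponentially-weighted quadrature),
#' with the refractory period added to the interval.
#'
#' @inheritParams fp_steady_state
#' @returns tibble with columns `rate_hz`, `cv`.
#' @export
fp_isi_cv <- function(params, mu, sigma, dv = 2^-4) {
  rc <- fp_rate_cv(params, mu, sigma, dv)
  tibble(rate_hz = rc$rate_hz, cv = rc$cv)
}

# ---- dominant nonzero eigenvalue ------------------------------------------

characteristic_residual <- function(g, params, lambda) {
  fp_complex_sweep_cpp(g$v, g$h, g$D, numeric(length(g$v)),
                       params$tau_m, g$i_reset - 1L, params$tau_ref,
                       Re(lambda), Im(lambda), 1, 0, g$p_top)[1]
}

newton_eigenvalue <- function(g, params, guess, tol = 1e-8, max_iter = 50) {
  lam <- guess
  f <- characteristic_residual(g, params, lam)
  f0 <- abs(f)
  for (it in seq_len(max_iter)) {
    h <- 1e-6 * max(abs(lam), 1e-3)
    fp <- characteristic_residual(g, params, lam + h)
    fm <- characteristic_residual(g, params, lam - h)
    dfdl <- (fp - fm) / (2 * h)
    if (abs(dfdl) == 0) return(NULL)
    step <- f / dfdl
    lam <- lam - step
    f <- characteristic_residual(g, params, lam)
    if (abs(step) < tol * max(abs(lam), 1e-4) && abs(f) < tol * max(f0, 1e-300))
      break
  }
  ok <- abs(f) < 1e-6 * max(f0, 1e-300) && Re(lam) < 0 &&
    abs(lam) > 0.05 * abs(guess)
  if (!ok) return(NULL)
  list(lambda = lam, residual = abs(f) / max(f0, 1e-300), iter = it)
}

#' Dominant nonzero Fokker-Planck eigenvalue
#'
#' The eigenvalue \eqn{\lambda_1} with the least negative real part governs
#' the decay rate (real part) and oscillation frequency (imaginary part) of
#' firing-rate transients. For the LIF and EIF it is located by
#' Newton-Raphson on the characteristic equation obtained by complex
#' threshold integration of the eigenmode (absorbing threshold, reset-flux
#' discontinuity carrying a factor \eqn{e^{-\lambda\tau_{ref}}}); on failure
#' the solver restarts from a lattice of 8 perturbed initial guesses. For
#' the QIF the membrane equation is transformed to the theta-model, whose
#' Fokker-Planck operator on the circle is expanded in a truncated Fourier
#' basis and diagonalized. The root with non-negative imaginary part is
#' reported (its conjugate is implied).
#'
#' @inheritParams fp_steady_state
#' @param guess complex initial guess (1/ms); default from the universal
#'   \eqn{\lambda(r_\infty, CV)} fit ([lambda_from_fit()]).
#' @param n_fourier truncation order for the QIF theta-model expansion.
#' @param dv voltage grid spacing (mV, LIF/EIF route).
#' @returns a `complex_eigenvalue` object.
#' @export
fp_eigenvalue <- function(params, mu, sigma, guess = NULL, n_fourier = 100,
                          dv = 2^-6) {
  stopifnot(inherits(params, "neuron_params"))
  if (sigma <= 0) abort("sigma must be positive")
  rc <- fp_rate_cv(params, mu, sigma)
  if (params$model == "qif") {
    res <- qif_eigen_fourier(params, mu, sigma, n_fourier)
    lam <- res$lambda
    residual <- res$gap
    method <- "theta_fourier"
  } else {
    g <- fp_grid(params, mu, sigma, dv)
    guess <- guess %||% lambda_from_fit(rc$rate_hz, max(rc$cv, 0.02))
    # Newton from the primary guess plus a lattice of 8 perturbed restarts;
    # nearby spurious/subdominant roots exist, so collect all converged
    # roots and keep the dominant one (largest real part)
    lattice <- expand.grid(fr = c(0.5, 1, 2), fi = c(0.6, 0.85, 1.15, 1.5, 2))
    starts <- c(guess, complex(real = Re(guess) * lattice$fr,
                               imaginary = Im(guess) * lattice$fi))
    roots <- list()
    for (s0 in starts) {
      fit <- newton_eigenvalue(g, params, s0)
      if (!is.null(fit)) roots[[length(roots) + 1]] <- fit
    }
    if (length(roots) == 0)
      abort(sprintf(
        "eigenvalue Newton-Raphson failed to converge (%s, mu=%.3g, sigma=%.3g)",
        params$model, mu, sigma))
    res <- vapply(roots, function(f) Re(f$lambda), numeric(1))
    fit <- roots[[which.max(res)]]
    lam <- fit$lambda
    residual <- fit$residual
    method <- "threshold_integration"
  }
  if (Im(lam) < 0) lam <- Conj(lam)
  structure(list(lambda = lam, model = params$model, mu = mu, sigma = sigma,
                 rate_hz = rc$rate_hz, cv = rc$cv, residual = residual,
                 method = method, params = params),
            class = "complex_eigenvalue")
}

#' @export
print.complex_eigenvalue <- function(x, ...) {
  cat(sprintf(
    "<lambda_1 %s: %.5f %+.5fi /ms  (r_inf = %.2f Hz, CV = %.3f)>\n",
    toupper(x$model), Re(x$lambda), Im(x$lambda), x$rate_hz, x$cv))
  invisible(x)
}

#' @method tidy complex_eigenvalue
#' @export
tidy.complex_eigenvalue <- function(x, ...) {
  tibble(model = x$model, mu = x$mu, sigma = x$sigma,
         rate_hz = x$rate_hz, cv = x$cv,
         lambda_re = Re(x$lambda), lambda_im = Im(x$lambda),
         decay_ms = -1 / Re(x$lambda),
         freq_hz = 1000 * Im(x$lambda) / (2 * pi),
         method = x$method)
}

# ---- QIF: theta-model Fourier machinery -----------------------------------

# Transformation V = b tan(theta/2) maps the QIF (threshold +Inf, reset
# -Inf) onto a diffusion on the circle; spikes are crossings of theta = pi.
# Ito drift A(theta) and noise B(theta) (see vignette):
#   A = [(b/Delta)(1-cos) + (mu_eff/b)(1+cos)]/tau - sig2/(2 tau b^2) *
#       (sin + sin2/2),   B^2 = (sig2/ tau b^2) (1+cos)^2
# where mu_eff absorbs the completed square of V(V-V_T)/Delta.
qif_theta_terms <- function(params, mu, sigma) {
  d <- params$delta_t
  vt <- params$v_t
  tau <- params$tau_m
  mu_eff <- mu - vt^2 / (4 * d) # f + mu = (V - vt/2)^2 / d + mu_eff
  b <- sqrt(d * max(abs(mu_eff), 1))
  s2 <- sigma^2
  list(
    b = b, tau = tau, d = d, mu_eff = mu_eff,
    a0 = (b / d + mu_eff / b) / tau,
    a1c = (mu_eff / b - b / d) / tau,
    a1s = -s2 / (2 * tau * b^2),
    a2s = -s2 / (4 * tau * b^2),
    c0 = 1.5 * s2 / (tau * b^2),
    c1 = 2 * s2 / (tau * b^2),
    c2 = 0.5 * s2 / (tau * b^2))
}

# Fourier-space generator: d c_m/dt = sum_k M[m, m-k] c_{m-k}
qif_theta_matrix <- function(params, mu, sigma, n_fourier = 100) {
  tt <- qif_theta_terms(params, mu, sigma)
  N <- n_fourier
  ms <- -N:N
  n <- length(ms)
  # complex Fourier coefficients of A and B^2 (index k = -2..2)
  A_k <- c(`-2` = complex(imaginary = tt$a2s / 2),
           `-1` = complex(real = tt$a1c / 2, imaginary = tt$a1s / 2),
           `0` = complex(real = tt$a0),
           `1` = complex(real = tt$a1c / 2, imaginary = -tt$a1s / 2),
           `2` = complex(imaginary = -tt$a2s / 2))
  C_k <- c(`-2` = tt$c2 / 2, `-1` = tt$c1 / 2, `0` = tt$c0,
           `1` = tt$c1 / 2, `2` = tt$c2 / 2)
  M <- matrix(0+0i, n, n)
  for (k in -2:2) {
    cols <- which(ms - k >= -N & ms - k <= N)
    for (i in cols) {
      jcol <- i - k # index of m - k  (ms are consecutive)
      m <- ms[i]
      M[i, jcol] <- M[i, jcol] -
        1i * m * A_k[[as.character(k)]] - 0.5 * m^2 * C_k[[as.character(k)]]
    }
  }
  attr(M, "terms") <- tt
  M
}

# derivative of the generator with respect to mu (b held fixed)
qif_theta_matrix_dmu <- function(params, mu, sigma, n_fourier = 100) {
  tt <- qif_theta_terms(params, mu, sigma)
  N <- n_fourier
  ms <- -N:N
  n <- length(ms)
  dA0 <- 1 / (tt$tau * tt$b)
  dA1 <- 1 / (2 * tt$tau * tt$b)
  M1 <- matrix(0+0i, n, n)
  for (k in -1:1) {
    dA <- if (k == 0) dA0 else dA1
    cols <- which(ms - k >= -N & ms - k <= N)
    for (i in cols) {
      M1[i, i - k] <- M1[i, i - k] - 1i * ms[i] * dA
    }
  }
  M1
}

qif_theta_stationary <- function(M) {
  tt <- attr(M, "terms")
  n <- nrow(M)
  N <- (n - 1) / 2
  i0 <- N + 1
  idx <- setdiff(seq_len(n), i0)
  # M c = 0 with c_0 = 1
  c_rest <- solve(M[idx, idx, drop = FALSE], -M[idx, i0])
  cc <- rep(0+0i, n)
  cc[i0] <- 1
  cc[idx] <- c_rest
  r_khz <- Re(tt$b / (pi * tt$d * tt$tau) * sum((-1)^abs(-N:N) * cc))
  list(c = cc, rate_hz = 1000 * r_khz)
}

qif_eigen_fourier <- function(params, mu, sigma, n_fourier = 100) {
  M <- qif_theta_matrix(params, mu, sigma, n_fourier)
  ev <- eigen(M, only.values = TRUE)$values
  i0 <- which.min(abs(ev))
  ev <- ev[-i0]
  ev <- ev[Re(ev) < 0]
  lam <- ev[which.max(Re(ev))]
  # spectral gap to the next mode, as a conditioning diagnostic
  rest <- ev[abs(ev - lam) > 1e-10 & abs(ev - Conj(lam)) > 1e-10]
  gap <- if (length(rest)) max(Re(rest)) - Re(lam) else NA_real_
  list(lambda = lam, gap = gap)
}

# ---- linear response -------------------------------------------------------

#' Linear response of the spiking models
#'
#' First-order firing-rate modulation for a sinusoidal perturbation of the
#' mean input, \eqn{I_0(t) = \mu + \epsilon\cos(\omega t)}. For the LIF and
#' EIF the first-order Fokker-Planck system is integrated by threshold
#' integration at each frequency (two sweeps whose superposition satisfies
#' the lower-boundary condition); for the QIF it is solved in the truncated
#' Fourier basis of the theta-model. The response is reported as gain
#' (Hz per mV of modulation) and phase lag (radians, positive = rate lags
#' the stimulus), unwrapped along the frequency grid.
#'
#' @inheritParams fp_steady_state
#' @param freq_hz vector of modulation frequencies (Hz), all positive.
#' @param n_fourier truncation order (QIF route).
#' @returns tibble with columns `freq_hz`, `gain_hz_per_mv`, `phase_rad`.
#' @export
fp_linear_response <- function(params, mu, sigma, freq_hz, n_fourier = 100,
                               dv = 2^-5) {
  stopifnot(all(freq_hz > 0))
  omega <- 2 * pi * freq_hz / 1000 # 1/ms
  if (params$model == "qif") {
    M <- qif_theta_matrix(params, mu, sigma, n_fourier)
    st <- qif_theta_stationary(M)
    tt <- attr(M, "terms")
    M1 <- qif_theta_matrix_dmu(params, mu, sigma, n_fourier)
    f0 <- M1 %*% st$c
    N <- (nrow(M) - 1) / 2
    signs <- (-1)^abs(-N:N)
    resp <- vapply(omega, function(w) {
      c1 <- solve(diag(1i * w, nrow(M)) - M, f0)
      tt$b / (pi * tt$d * tt$tau) * sum(signs * c1)
    }, complex(1))
  } else {
    st <- fp_steady_state(params, mu, sigma, dv)
    g <- fp_grid(params, mu, sigma, dv)
    p0 <- st$density$p0
    resp <- vapply(omega, function(w) {
      za <- fp_complex_sweep_cpp(g$v, g$h, g$D, p0, params$tau_m,
                                 g$i_reset - 1L, params$tau_ref, 0, w,
                                 1, 0, g$p_top)
      zb <- fp_complex_sweep_cpp(g$v, g$h, g$D, p0, params$tau_m,
                                 g$i_reset - 1L, params$tau_ref, 0, w,
                                 0, 1, g$p_top)
      -zb[1] / za[1]
    }, complex(1))
  }
  tibble(freq_hz = freq_hz,
         gain_hz_per_mv = 1000 * Mod(resp),
         phase_rad = unwrap_phase(-Arg(resp)))
}

unwrap_phase <- function(ph) {
  if (length(ph) < 2) return(ph)
  d <- diff(ph)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  ph - 2 * pi * jumps
}

# ---- PDE transient oracle --------------------------------------------------

#' Fokker-Planck transient by direct PDE integration
#'
#' Method-of-lines integration (Crank-Nicolson in time,
#' Scharfetter-Gummel exponential-fitting fluxes in voltage) of the full
#' Fokker-Planck equation after an instantaneous step of the mean input from
#' `mu0` to `mu1`, starting from the stationary density at `mu0`. Serves as
#' an independent check on the spectral solvers: fitting a damped cosine to
#' the rate transient recovers \eqn{\lambda_1}.
#'
#' @inheritParams fp_steady_state
#' @param mu0,mu1 pre- and post-step mean input (mV).
#' @param duration integration time after the step (ms).
#' @param dt_pde PDE time step (ms).
#' @returns tibble with columns `time_ms`, `rate_hz`.
#' @export
fp_pde_transient <- function(params, mu0, mu1, sigma, duration = 150,
                             dt_pde = 0.01, dv = 2^-5) {
  g1 <- fp_grid(params, mu1, sigma, dv)
  # stationary density at mu0 evaluated on the mu1 grid
  h0 <- membrane_drift(g1$v, params, mu0) / params$tau_m
  p_top0 <- if (params$model == "lif") 0 else
    params$tau_m / membrane_drift(g1$v[length(g1$v)], params, mu0)
  st0 <- fp_steady_cpp(g1$v, h0, g1$D, g1$i_reset - 1L, params$tau_ref, p_top0)
  tail0 <- if (params$model == "qif") qif_tail_total(params, mu0) else 0
  r0 <- 1 / (st0$mass + tail0 + params$tau_ref) # kHz
  p_init <- r0 * st0$p
  n_steps <- round(duration / dt_pde)
  loop_delay <- params$tau_ref +
    if (params$model == "qif") qif_tail_total(params, mu1) else 0
  ref_steps <- max(1L, as.integer(round(loop_delay / dt_pde)))
  be_steps <- as.integer(round(1 / dt_pde)) # 1 ms of damped startup steps
  r <- fp_pde_cpp(g1$v, g1$h, g1$D, g1$i_reset - 1L, ref_steps, dt_pde,
                  n_steps, p_init[-length(p_init)], r0, be_steps)
  tibble(time_ms = seq_len(n_steps) * dt_pde, rate_hz = 1000 * r)
}

#' Fit a damped cosine to a rate transient
#'
#' Least-squares fit of \eqn{r(t) = r_\infty + A e^{\alpha t}
#' \cos(\omega t + \phi)} over a window, used to extract decay rate and
#' oscillation frequency from PDE or Monte-Carlo transients. Initial
#' frequency from the discrete spectrum of the windowed trace; `r_inf` from
#' the trailing samples.
#'
#' @param time_ms,rate_hz the transient.
#' @param blank_ms initial blanking period excluded from the fit.
#' @param window_ms fit window after the blanking period.
#' @returns tibble with `alpha` (1/ms), `omega` (1/ms), `freq_hz`,
#'   `r_inf_hz`, `amp`, `sse`.
#' @export
fit_damped_cosine <- function(time_ms, rate_hz, blank_ms = 20,
                              window_ms = 100) {
  keep <- time_ms > blank_ms & time_ms <= blank_ms + window_ms
  t <- time_ms[keep] - blank_ms
  y <- rate_hz[keep]
  r_inf <- mean(rate_hz[time_ms > max(time_ms) - 0.1 * max(time_ms)])
  z <- y - r_inf
  # spectral initial guess for omega
  n <- length(z)
  sp <- Mod(fft(z * (0.5 - 0.5 * cos(2 * pi * seq_len(n) / n))))[2:floor(n / 2)]
  dt <- t[2] - t[1]
  fbins <- seq_along(sp) / (n * dt) # cycles per ms
  sp[fbins > 0.3] <- 0 # restrict the search to < 300 Hz
  f0 <- fbins[which.max(sp)]
  w0 <- 2 * pi * f0
  a0 <- log(max(abs(z[seq_len(ceiling(n / 10))])) /
              max(abs(z[(n - ceiling(n / 10)):n]), 1e-12)) / (-t[n]) * 1.0
  a0 <- min(a0, -1e-4)
  obj <- function(par) {
    al <- par[1]; w <- par[2]; A <- par[3]; ph <- par[4]
    if (!is.finite(al) || al > 0.05 || abs(w) > 2.5) return(1e12)
    sum((z - A * exp(al * t) * cos(w * t + ph))^2)
  }
  best <- NULL
  for (ph0 in c(0, pi / 2, pi, -pi / 2)) {
    fit <- stats::optim(c(a0, w0, max(abs(z)), ph0), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  al <- best$par[1]; w <- abs(best$par[2])
  tibble(alpha = al, omega = w, freq_hz = 1000 * w / (2 * pi),
         r_inf_hz = r_inf, amp = best$par[3], sse = best$value)
}
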