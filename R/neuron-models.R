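# Integrate-and-fire model definitions: membrane drift, threshold/reset rules
# and the stochastic input-current description.

#' Integrate-and-fire neuron parameters
#'
#' Builds a validated parameter set for one of the three integrate-and-fire
#' variants. The membrane equation is
#' \deqn{\tau_m \, dV/dt = f(V) + I(t),}
#' with \eqn{f(V) = -(V - E_L)} for the leaky (LIF) model,
#' \eqn{f(V) = V (V - V_T)/\Delta_T} for the quadratic (QIF) model and
#' \eqn{f(V) = -(V - E_L) + \Delta_T \exp[(V - V_T)/\Delta_T]} for the
#' exponential (EIF) model. The QIF and EIF generate spikes by a finite-time
#' blow-up, so their nominal threshold lies at infinity; numerically a spike
#' is registered when \eqn{V} crosses the ceiling `v_ceiling`, and for the
#' QIF the deterministic traversal time of the two discarded tails is added
#' back as a spike latency (see [tail_times()]).
#'
#' Default values (mV, ms):
#'
#' | parameter | QIF | EIF | LIF |
#' |-----------|-----|-----|-----|
#' | `v_th`      | Inf | Inf | 20 |
#' | `v_t`       | 0   | 10  | -  |
#' | `e_l`       | -   | 0   | 0  |
#' | `v_reset`   | -Inf| 3   | 10 |
#' | `tau_m`     | 10  | 10  | 10 |
#' | `tau_ref`   | 0   | 2   | 0  |
#' | `delta_t`   | 10  | 1   | -  |
#'
#' @param model one of `"lif"`, `"qif"`, `"eif"`.
#' @param v_th spike threshold (mV); `Inf` for QIF/EIF.
#' @param v_reset reset potential (mV); `-Inf` for the QIF.
#' @param e_l leak reversal potential (mV).
#' @param v_t soft-threshold potential (mV, QIF/EIF).
#' @param delta_t spike sharpness (mV); for the QIF this is the curvature
#'   scale of the quadratic nonlinearity.
#' @param tau_m membrane time constant (ms).
#' @param tau_ref absolute refractory period (ms).
#' @param v_ceiling numerical stand-in for the infinite threshold (mV).
#'   Defaults: `v_t + 10 * delta_t` for the EIF, `300` for the QIF, `v_th`
#'   for the LIF.
#' @param v_floor numerical lower bound for simulations (mV).
#' @returns an object of class `neuron_params`.
#' @export
#' @examples
#' p <- neuron_params("eif")
#' membrane_drift(c(-10, 0, 10), p, input_mean = 5)
neuron_params <- function(model = c("lif", "qif", "eif"),
                          v_th = NULL, v_reset = NULL, e_l = NULL,
                          v_t = NULL, delta_t = NULL, tau_m = 10,
                          tau_ref = NULL, v_ceiling = NULL, v_floor = NULL) {
  model <- match.arg(model)
  def <- switch(model,
    lif = list(v_th = 20, v_reset = 10, e_l = 0, v_t = NA_real_,
               delta_t = NA_real_, tau_ref = 0),
    qif = list(v_th = Inf, v_reset = -Inf, e_l = NA_real_, v_t = 0,
               delta_t = 10, tau_ref = 0),
    eif = list(v_th = Inf, v_reset = 3, e_l = 0, v_t = 10,
               delta_t = 1, tau_ref = 2))
  v_th    <- v_th    %||% def$v_th
  v_reset <- v_reset %||% def$v_reset
  e_l     <- e_l     %||% def$e_l
  v_t     <- v_t     %||% def$v_t
  delta_t <- delta_t %||% def$delta_t
  tau_ref <- tau_ref %||% def$tau_ref

  if (tau_m <= 0) abort("`tau_m` must be positive")
  if (tau_ref < 0) abort("`tau_ref` must be non-negative")
  if (!(v_reset < v_th)) abort("`v_reset` must lie below `v_th`")
  if (model == "eif" && !(isTRUE(delta_t > 0)))
    abort("`delta_t` must be positive for the EIF")
  if (model == "qif" && !(isTRUE(delta_t > 0)))
    abort("`delta_t` must be positive for the QIF")

  if (is.null(v_ceiling)) {
    v_ceiling <- switch(model,
      lif = v_th,
      eif = v_t + 10 * delta_t,
      qif = 300)
  }
  if (is.null(v_floor)) {
    v_floor <- switch(model,
      lif = v_reset - 100,
      eif = v_reset - 100,
      qif = -v_ceiling)
  }
  if (v_ceiling < min(v_th, v_ceiling)) abort("`v_ceiling` below threshold")
  structure(
    list(model = model, v_th = v_th, v_reset = v_reset, e_l = e_l,
         v_t = v_t, delta_t = delta_t, tau_m = tau_m, tau_ref = tau_ref,
         v_ceiling = v_ceiling, v_floor = v_floor),
    class = "neuron_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params: %s>\n", toupper(x$model)))
  flds <- c("v_th", "v_reset", "e_l", "v_t", "delta_t", "tau_m", "tau_ref",
            "v_ceiling", "v_floor")
  for (f in flds) cat(sprintf("  %-9s %s\n", f, format(x[[f]])))
  invisible(x)
}

model_code <- function(params) {
  match(params$model, c("lif", "qif", "eif")) - 1L
}

# drift parameters with NA fields replaced by inert values for the C++ kernel
drift_args <- function(params) {
  list(kind = model_code(params),
       e_l = if (is.na(params$e_l)) 0 else params$e_l,
       v_t = if (is.na(params$v_t)) 0 else params$v_t,
       delta_t = if (is.na(params$delta_t)) 1 else params$delta_t)
}

#' Deterministic membrane drift
#'
#' Evaluates the full right-hand side \eqn{f(V) + I_0} of the membrane
#' equation, in mV per membrane time constant.
#'
#' @param v membrane potential(s), mV.
#' @param params a [neuron_params()] object.
#' @param input_mean constant input current \eqn{I_0} (mV).
#' @returns numeric vector, same length as `v`.
#' @export
membrane_drift <- function(v, params, input_mean = 0) {
  stopifnot(inherits(params, "neuron_params"))
  da <- drift_args(params)
  drift_f_cpp(da$kind, as.numeric(v), da$e_l, da$v_t, da$delta_t) + input_mean
}

#' Threshold crossing and reset
#'
#' Applies the spike rule: if `v` is at or above the effective threshold
#' (`v_th` for the LIF, the numerical ceiling for QIF/EIF) a spike is
#' reported and the potential is reset. Refractory clamping is the caller's
#' responsibility.
#'
#' @inheritParams membrane_drift
#' @returns a tibble with columns `spiked` (logical) and `v_new` (mV).
#' @export
spike_and_reset <- function(v, params) {
  stopifnot(inherits(params, "neuron_params"))
  thr <- min(params$v_th, params$v_ceiling)
  spiked <- v >= thr
  v_new <- ifelse(spiked, max(params$v_reset, params$v_floor), v)
  tibble(spiked = spiked, v_new = v_new)
}

#' Deterministic tail traversal times for ceiling-truncated models
#'
#' For the QIF the spike trajectory escapes to \eqn{+\infty} and re-enters
#' from \eqn{-\infty}; truncating at `±v_ceiling` discards a deterministic
#' traversal time \eqn{\tau_m \int dV/(f(V)+\mu)} per tail, which is added
#' back as spike latency (`up`) and reset hold (`down`). Negligible for the
#' EIF (exponentially fast tail) and absent for the LIF.
#'
#' @inheritParams membrane_drift
#' @param input_mean mean drive used for the tail integral (mV).
#' @returns list with elements `up` and `down` (ms).
#' @export
tail_times <- function(params, input_mean = 0) {
  if (params$model != "qif") return(list(up = 0, down = 0))
  mu <- input_mean
  d <- params$delta_t
  tau <- params$tau_m
  vb <- params$v_ceiling
  # int_vb^Inf tau dV / (V(V - v_t)/d + mu); complete the square
  vt <- params$v_t
  a <- -vt / 2
  q <- mu - vt^2 / (4 * d)  # f + mu = (V + a)^2 / d + q
  tail_int <- function(lo) {
    # int_lo^Inf tau dV / ((V + a)^2 / d + q)
    if (q > 1e-12) {
      s <- sqrt(q * d)
      tau * d / s * (pi / 2 - atan((lo + a) / s))
    } else if (q < -1e-12) {
      s <- sqrt(-q * d)
      x <- (lo + a) / s
      if (x <= 1) return(Inf) # trajectory never escapes: subthreshold
      tau * d / (2 * s) * log((x + 1) / (x - 1))
    } else {
      tau * d / (lo + a)
    }
  }
  up <- tail_int(vb)
  down <- tail_int(vb - 2 * a) # symmetric tail: |-v_ceiling - a| = vb + a
  list(up = up, down = down)
}

#' Stochastic input-current description
#'
#' The input current of the population model is
#' \eqn{I(t) = I_0(t) + \sigma(t)\sqrt{\tau_m}\,\eta(t)} with
#' \eqn{\langle\eta(t)\eta(t')\rangle = \delta(t-t')} (the default
#' `"sqrt_tau"` convention, under which the free membrane voltage variance is
#' \eqn{\sigma^2/2}). The alternative `"plain"` convention omits the
#' \eqn{\sqrt{\tau_m}} factor.
#'
#' @param mean the common mean \eqn{I_0(t)}: a scalar, a numeric vector
#'   sampled on the simulation step grid, or a function of time (ms).
#' @param sd the noise amplitude \eqn{\sigma(t)} (mV), same forms as `mean`.
#' @param convention white-noise scaling convention.
#' @returns an object of class `input_drive`.
#' @export
input_drive <- function(mean, sd, convention = c("sqrt_tau", "plain")) {
  convention <- match.arg(convention)
  structure(list(mean = mean, sd = sd, convention = convention),
            class = "input_drive")
}

# sample a drive component on a step grid (values at step midpoints t_k = k*dt)
sample_drive <- function(x, n_steps, dt) {
  t <- (seq_len(n_steps) - 1) * dt
  out <- if (is.function(x)) x(t)
  else if (length(x) == 1) rep(as.numeric(x), n_steps)
  else if (length(x) == n_steps) as.numeric(x)
  else abort("drive component has wrong length for the step grid")
  out
}

# effective sigma for the C++ kernels, which assume the sqrt_tau convention
effective_sigma <- function(drive, sig, tau_m) {
  if (drive$convention == "plain") sig / sqrt(tau_m) else sig
}

#' Read or write neuron parameters as flat JSON
#'
#' Parameter files are flat key-value JSON objects mirroring the
#' [neuron_params()] fields, one block per model.
#'
#' @param path file path.
#' @returns `read_neuron_params()`: a [neuron_params()] object.
#' @export
read_neuron_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num_fields <- setdiff(names(x), "model")
  x[num_fields] <- lapply(x[num_fields], function(v) suppressWarnings(as.numeric(v)))
  do.call(neuron_params, x)
}

#' @rdname read_neuron_params
#' @param params a [neuron_params()] object.
#' @export
write_neuron_params <- function(params, path) {
  stopifnot(inherits(params, "neuron_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
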