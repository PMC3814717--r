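# Monte-Carlo simulation of uncoupled populations: spike rasters, PSTH rate
# estimates and interspike-interval statistics.

#' Simulate an uncoupled population of integrate-and-fire neurons
#'
#' Euler-Maruyama integration of the membrane equation for `n_neurons`
#' identical neurons sharing the common mean input and receiving independent
#' white noise. Thresholds are handled at step granularity; for the QIF the
#' deterministic traversal times of the truncated tails are added back as
#' spike latency and reset hold (see [tail_times()]).
#'
#' @param params a [neuron_params()] object.
#' @param drive an [input_drive()]; mean/sd may be scalars, functions of time
#'   (ms) or vectors on the step grid.
#' @param n_neurons number of neurons.
#' @param duration simulated time (ms).
#' @param dt integration step (ms). Defaults: 0.05 for the LIF, 0.02 for
#'   QIF/EIF (stiff near the ceiling).
#' @param seed integer seed (counter-based per-neuron streams).
#' @param v0 initial potential (mV); default `v_reset`.
#' @returns a `spike_raster`: tibble with columns `time_ms`, `neuron` and
#'   attributes `n_neurons`, `duration`, `params`.
#' @export
#' @examples
#' p <- neuron_params("lif")
#' r <- simulate_population(p, input_drive(25, 1), n_neurons = 20,
#'                          duration = 500, seed = 1)
#' isi_statistics(r)
simulate_population <- function(params, drive, n_neurons, duration,
                                dt = NULL, seed = 1L, v0 = NULL) {
  stopifnot(inherits(params, "neuron_params"), inherits(drive, "input_drive"))
  dt <- dt %||% if (params$model == "lif") 0.05 else 0.02
  if (params$tau_m / dt < 100)
    warn("time step is coarse relative to the membrane time constant")
  n_steps <- round(duration / dt)
  i0 <- sample_drive(drive$mean, n_steps, dt)
  sig <- effective_sigma(drive, sample_drive(drive$sd, n_steps, dt),
                         params$tau_m)
  if (any(sig < 0)) abort("noise sd must be non-negative")
  da <- drift_args(params)
  tails <- tail_times(params, mean(i0))
  delay_steps <- as.integer(round(tails$up / dt))
  hold_steps <- as.integer(round((tails$up + tails$down) / dt))
  v0 <- v0 %||% max(params$v_reset, params$v_floor)
  out <- simulate_population_cpp(
    da$kind, da$e_l, da$v_t, da$delta_t, params$tau_m, params$tau_ref,
    min(params$v_th, params$v_ceiling), max(params$v_reset, params$v_floor),
    params$v_floor, i0, sig, as.integer(n_neurons), dt, as.double(seed),
    v0, delay_steps, hold_steps)
  new_spike_raster(tibble(time_ms = out$time_ms, neuron = out$neuron),
                   n_neurons = n_neurons, duration = duration,
                   params = params)
}

new_spike_raster <- function(df, n_neurons, duration, params = NULL) {
  structure(df, class = c("spike_raster", class(df)),
            n_neurons = n_neurons, duration = duration, params = params)
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster: %d spikes, %d neurons, %.0f ms>\n",
              nrow(x), attr(x, "n_neurons"), attr(x, "duration")))
  NextMethod()
}

#' Population rate estimate (PSTH)
#'
#' Bins spikes and divides by `n_neurons * bin`, with optional Gaussian
#' kernel smoothing. Smoothing preserves the time-integral of the rate.
#'
#' @param raster a `spike_raster`.
#' @param bin_ms bin width (ms).
#' @param smooth_ms Gaussian kernel standard deviation (ms); 0 disables.
#' @param n_neurons population size normalizing the PSTH; defaults to the
#'   raster attribute (override when the raster was subset to one
#'   population).
#' @returns a `population_rate`: tibble with `time_ms` (bin centers) and
#'   `rate_hz`.
#' @export
estimate_rate <- function(raster, bin_ms = 1, smooth_ms = 0,
                          n_neurons = NULL) {
  stopifnot(bin_ms > 0)
  duration <- attr(raster, "duration")
  n_neurons <- n_neurons %||% attr(raster, "n_neurons")
  edges <- seq(0, duration + bin_ms * 1e-9, by = bin_ms)
  if (edges[length(edges)] < duration) edges <- c(edges, duration)
  counts <- if (nrow(raster) == 0) {
    rep(0, length(edges) - 1)
  } else {
    tabulate(findInterval(pmin(raster$time_ms, duration - 1e-9), edges),
             nbins = length(edges) - 1)
  }
  rate <- counts / (n_neurons * bin_ms) * 1000 # Hz
  if (smooth_ms > 0) rate <- gaussian_smooth(rate, smooth_ms / bin_ms)
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  structure(tibble(time_ms = centers, rate_hz = rate),
            class = c("population_rate", class(tibble())),
            bin_ms = bin_ms, smooth_ms = smooth_ms, n_neurons = n_neurons)
}

# discrete Gaussian smoothing with a normalized kernel; mass smoothed past
# the edges is folded back so the time-integral is preserved exactly
gaussian_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_bins))
  k <- dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  n <- length(x)
  xx <- c(rep(0, 2 * half), x, rep(0, 2 * half))
  full <- as.numeric(stats::filter(xx, k, sides = 2))
  sm <- full[(half + 1):(3 * half + n)] # positions 1-half .. n+half
  out <- sm[(half + 1):(half + n)]
  out[1] <- out[1] + sum(sm[1:half])
  out[n] <- out[n] + sum(sm[(half + n + 1):(n + 2 * half)])
  out
}

#' Interspike-interval statistics of a raster
#'
#' Pools interspike intervals across neurons after discarding an initial
#' transient and returns the mean firing rate (inverse mean ISI) and the
#' coefficient of variation.
#'
#' @param raster a `spike_raster`.
#' @param discard_ms transient to discard (ms).
#' @param min_isi minimum number of pooled ISIs required.
#' @returns tibble with columns `rate_hz`, `cv`, `n_isi`.
#' @export
isi_statistics <- function(raster, discard_ms = 200, min_isi = 100) {
  df <- raster[raster$time_ms >= discard_ms, , drop = FALSE]
  isis <- unlist(lapply(split(df$time_ms, df$neuron), function(tt) {
    if (length(tt) < 2) return(numeric(0))
    diff(sort(tt))
  }), use.names = FALSE)
  if (length(isis) < min_isi)
    abort(sprintf("only %d ISIs after the transient (need >= %d)",
                  length(isis), min_isi))
  m <- mean(isis)
  tibble(rate_hz = 1000 / m, cv = sd(isis) / m, n_isi = length(isis))
}

#' @importFrom stats dnorm
NULL
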