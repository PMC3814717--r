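# Common-input protocols: steps, random-phase sinusoid mixtures, constants,
# piecewise-constant segments, plus the per-neuron independent noise streams.

#' Common-input stimulus specification
#'
#' Describes the shared input \eqn{I_0(t)} delivered to every neuron of a
#' population. Four kinds are supported:
#' * `"constant"`: flat at `baseline`.
#' * `"step"`: `baseline`, jumping by `amplitude` at `onset`.
#' * `"sinusoid_mix"`: `baseline` plus equal-amplitude sinusoids at
#'   `frequencies` with phases drawn uniformly on \eqn{[0, 2\pi)} from a
#'   dedicated seeded stream. The default frequencies are
#'   61, 50, 33, 13.1 and 7.9 Hz.
#' * `"piecewise"`: right-continuous steps through `values` at `times`.
#'
#' @param kind stimulus kind.
#' @param baseline baseline mean input (mV).
#' @param amplitude step height or per-sinusoid amplitude (mV).
#' @param onset step onset time (ms).
#' @param frequencies sinusoid frequencies (Hz).
#' @param phases optional explicit phases (radians); if `NULL` they are drawn
#'   from `seed`.
#' @param times,values change points (ms) and levels (mV) for `"piecewise"`.
#' @param duration total duration (ms).
#' @param dt sample step (ms).
#' @param seed integer seed for the random phases.
#' @returns an object of class `stimulus_spec`.
#' @export
#' @examples
#' spec <- stimulus_spec("sinusoid_mix", baseline = 10, amplitude = 0.5,
#'                       duration = 1000, seed = 1)
#' stim <- render_common_input(spec)
stimulus_spec <- function(kind = c("constant", "step", "sinusoid_mix",
                                   "piecewise"),
                          baseline = 0, amplitude = 0, onset = 0,
                          frequencies = c(61, 50, 33, 13.1, 7.9),
                          phases = NULL, times = NULL, values = NULL,
                          duration = 1000, dt = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  if (duration <= 0) abort("`duration` must be positive")
  if (dt <= 0) abort("`dt` must be positive")
  if (kind == "sinusoid_mix") {
    if (length(frequencies) == 0)
      abort("`frequencies` must be non-empty for a sinusoid mixture")
    if (any(frequencies <= 0)) abort("`frequencies` must be positive")
    if (is.null(phases)) {
      # dedicated sub-stream so phases do not depend on other draws
      phases <- withr_seed(seed, function() runif(length(frequencies), 0, 2 * pi))
    }
    if (length(phases) != length(frequencies))
      abort("`phases` must match `frequencies` in length")
  }
  if (kind == "piecewise") {
    if (is.null(times) || is.null(values) || length(times) != length(values))
      abort("`times` and `values` must be equal-length for piecewise input")
  }
  structure(list(kind = kind, baseline = baseline, amplitude = amplitude,
                 onset = onset, frequencies = frequencies, phases = phases,
                 times = times, values = values, duration = duration,
                 dt = dt, seed = seed),
            class = "stimulus_spec")
}

# evaluate f() under a local RNG state seeded with `seed`
withr_seed <- function(seed, f) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  f()
}

#' Render the common input on its sample grid
#'
#' @param spec a [stimulus_spec()].
#' @returns a tibble with columns `time_ms`, `i0_mv`.
#' @export
render_common_input <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- round(spec$duration / spec$dt)
  t <- (seq_len(n) - 1) * spec$dt
  i0 <- switch(spec$kind,
    constant = rep(spec$baseline, n),
    step = spec$baseline + spec$amplitude * (t >= spec$onset),
    sinusoid_mix = {
      s <- rep(spec$baseline, n)
      for (k in seq_along(spec$frequencies)) {
        s <- s + spec$amplitude *
          sin(2 * pi * spec$frequencies[k] * t / 1000 + spec$phases[k])
      }
      s
    },
    piecewise = {
      idx <- findInterval(t, spec$times)
      c(spec$baseline, spec$values)[idx + 1]
    })
  tibble(time_ms = t, i0_mv = i0)
}

#' Independent per-neuron Gaussian noise increments
#'
#' Draws the matrix of Wiener increments used by the Euler-Maruyama
#' simulators: independent \eqn{N(0, dt)} variables, one row per neuron.
#' Rows are generated from per-neuron counter-based streams (stream index =
#' neuron index), so enlarging the population leaves existing rows unchanged.
#'
#' @param n_neurons,n_steps matrix dimensions.
#' @param dt time step (ms); increments have variance `dt`.
#' @param seed integer seed.
#' @returns an `n_neurons` by `n_steps` numeric matrix.
#' @export
draw_noise_increments <- function(n_neurons, n_steps, dt, seed) {
  stopifnot(n_neurons >= 1, n_steps >= 1, dt > 0)
  noise_increments_cpp(as.integer(n_neurons), as.integer(n_steps), dt,
                       as.double(seed))
}
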