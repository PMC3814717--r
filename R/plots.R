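# ggplot2 display methods for the package result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_raster labs scale_fill_manual scale_y_log10 facet_wrap theme_minimal
#' @importFrom generics tidy glance
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Plot a spike raster
#'
#' @param object a `spike_raster`.
#' @param max_neurons show at most this many neurons.
#' @param ... unused.
#' @returns a ggplot.
#' @method autoplot spike_raster
#' @export
autoplot.spike_raster <- function(object, max_neurons = 200, ...) {
  df <- object[object$neuron < max_neurons, , drop = FALSE]
  ggplot(df, aes(x = .data$time_ms, y = .data$neuron)) +
    geom_point(shape = ".", alpha = 0.6) +
    labs(x = "time (ms)", y = "neuron") +
    theme_minimal()
}

#' Plot a population-rate trace
#'
#' @param object a `population_rate`.
#' @param ... unused.
#' @returns a ggplot.
#' @method autoplot population_rate
#' @export
autoplot.population_rate <- function(object, ...) {
  ggplot(object, aes(x = .data$time_ms, y = .data$rate_hz)) +
    geom_line() +
    labs(x = "time (ms)", y = "rate (Hz)") +
    theme_minimal()
}

#' Plot an operating table field
#'
#' @param object an `operating_table`.
#' @param field one of `"rate_hz"`, `"cv"`, `"lambda_re"`, `"lambda_im"`.
#' @param ... unused.
#' @returns a ggplot.
#' @method autoplot operating_table
#' @export
autoplot.operating_table <- function(object, field = "rate_hz", ...) {
  ggplot(object, aes(x = .data$mu, y = .data$sigma,
                     fill = .data[[field]])) +
    geom_tile() +
    labs(x = expression(mu ~ "(mV)"), y = expression(sigma ~ "(mV)"),
         fill = field) +
    theme_minimal()
}

#' Plot a stability phase diagram
#'
#' Limit-cycle cells shaded, stable-fixed-point cells white, matching the
#' usual presentation of synchrony transition diagrams.
#'
#' @param object a `stability_map`.
#' @param ... unused.
#' @returns a ggplot.
#' @method autoplot stability_map
#' @export
autoplot.stability_map <- function(object, ...) {
  ggplot(object, aes(x = .data$w_e, y = .data$w_i, fill = .data$verdict)) +
    geom_tile(color = "grey80") +
    scale_fill_manual(values = c(stable_fixed_point = "white",
                                 limit_cycle = "orange",
                                 no_fixed_point = "grey40")) +
    labs(x = expression(w[E] ~ "(mV)"), y = expression(w[I] ~ "(mV)")) +
    theme_minimal()
}

#' Glance at a stability map
#'
#' @param x a `stability_map`.
#' @param ... unused.
#' @returns one-row tibble with cell counts per verdict.
#' @method glance stability_map
#' @export
glance.stability_map <- function(x, ...) {
  tibble(n_cells = nrow(x),
         n_limit_cycle = sum(x$verdict == "limit_cycle"),
         n_stable = sum(x$verdict == "stable_fixed_point"),
         n_failed = sum(x$verdict == "no_fixed_point"))
}
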