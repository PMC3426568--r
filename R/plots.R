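#' Raster plot of a simulation
#'
#' Spike raster folded by daily period: one row per period, spike phase on
#' the horizontal axis, with the day/night boundary marked. This is the
#' standard at-a-glance view of sleep-wake cycle quality.
#'
#' @param object A `somnox_sim`.
#' @param neuron Neuron to plot (default `"B"`).
#' @param f_w Wake fraction marking the day/night split (default 2/3).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.somnox_sim <- function(object, neuron = "B", f_w = 2 / 3, ...) {
  T <- object$config$stimulus$period
  st <- object$spike_times[[neuron]]
  df <- tibble::tibble(period = floor(st / T), phase = (st %% T) / 1000)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$period)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::geom_vline(xintercept = f_w * T / 1000, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_reverse(breaks = unique(df$period)) +
    ggplot2::labs(x = "time within period (s)", y = "period",
                  title = sprintf("Raster of neuron %s", neuron)) +
    ggplot2::theme_minimal()
}

#' Q-versus-disorder curve of a sweep
#'
#' Per-seed points and the seed-averaged curve of the sleep-wake quality
#' coefficient against the swept disorder magnitude (noise intensity or
#' diversity width).
#'
#' @param object A `somnox_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.somnox_sweep <- function(object, ...) {
  res <- object$results
  m <- dplyr::summarise(dplyr::group_by(res, .data$value),
                        Q = mean(.data$Q), .groups = "drop")
  xlab <- if (object$kind %in% c("divBA", "divAB"))
    "diversity width w (mV)" else "noise intensity D"
  ggplot2::ggplot(res, ggplot2::aes(x = .data$value, y = .data$Q)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = m, linewidth = 0.8, colour = "firebrick") +
    ggplot2::labs(x = xlab, y = "quality coefficient Q",
                  title = sprintf("%s sweep", object$kind)) +
    ggplot2::theme_minimal()
}

#' Trace plot of the slow homeostatic variables
#'
#' Down-sampled membrane potential of neuron B together with the population
#' means of the orexin availability and orexin-current activation.
#'
#' @param sim A `somnox_sim` run with `record_traces = TRUE`.
#' @return A ggplot object.
#' @export
plot_traces <- function(sim) {
  if (is.null(sim$traces)) stop("simulation was run without traces")
  long <- tidyr::pivot_longer(sim$traces, -"t_ms", names_to = "variable",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_ms / 1000,
                                     y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
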