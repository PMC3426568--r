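#' Tidy a quality-coefficient report
#'
#' One row per retained period with the day and night wake times and their
#' fractions of the respective windows.
#'
#' @param x A `somnox_qreport`.
#' @param ... Unused.
#' @return A tibble with columns `period`, `W_day_ms`, `W_night_ms`,
#'   `day_fraction`, `night_fraction`.
#' @export
tidy.somnox_qreport <- function(x, ...) {
  dplyr::mutate(x$periods,
                day_fraction = .data$W_day_ms / (x$f_w * x$T),
                night_fraction = .data$W_night_ms / ((1 - x$f_w) * x$T))
}

#' Glance at a quality-coefficient report
#' @param x A `somnox_qreport`.
#' @param ... Unused.
#' @return A one-row tibble with `Q`, `f_w`, `T`, `n_periods`,
#'   `mean_day_wake_ms`, `mean_night_wake_ms`.
#' @export
glance.somnox_qreport <- function(x, ...) {
  tibble::tibble(Q = x$Q, f_w = x$f_w, T = x$T,
                 n_periods = nrow(x$periods),
                 mean_day_wake_ms = mean(x$periods$W_day_ms),
                 mean_night_wake_ms = mean(x$periods$W_night_ms))
}

#' Tidy a disorder sweep
#' @param x A `somnox_sweep`.
#' @param ... Unused.
#' @return The per-run results tibble (`kind`, `value`, `seed`, `Q`,
#'   `periodicity`, `night_wake_ms`).
#' @export
tidy.somnox_sweep <- function(x, ...) x$results

#' Glance at a disorder sweep
#'
#' Summarises the Q-versus-disorder curve: the location and height of its
#' maximum (seed-averaged) and the endpoint values.
#'
#' @param x A `somnox_sweep`.
#' @param ... Unused.
#' @return A one-row tibble with `kind`, `n_values`, `n_seeds`,
#'   `optimal_value`, `Q_max`, `Q_first`, `Q_last`.
#' @export
glance.somnox_sweep <- function(x, ...) {
  m <- dplyr::summarise(dplyr::group_by(x$results, .data$value),
                        Q = mean(.data$Q), .groups = "drop")
  i <- which.max(m$Q)
  tibble::tibble(kind = x$kind,
                 n_values = nrow(m),
                 n_seeds = length(unique(x$results$seed)),
                 optimal_value = m$value[i],
                 Q_max = m$Q[i],
                 Q_first = m$Q[1],
                 Q_last = m$Q[nrow(m)])
}

#' Tidy a simulation's spike record
#' @param x A `somnox_sim`.
#' @param ... Unused.
#' @return The spikes tibble (`neuron_id`, `t_ms`).
#' @export
tidy.somnox_sim <- function(x, ...) x$spikes

#' Glance at a simulation
#' @param x A `somnox_sim`.
#' @param ... Unused.
#' @return A one-row tibble with `N`, `duration_ms`, `dt_ms`, `seed`,
#'   `n_spikes_B`, `n_spikes_A`.
#' @export
glance.somnox_sim <- function(x, ...) {
  nb <- length(x$spike_times[["B"]])
  tibble::tibble(N = x$config$N, duration_ms = x$duration, dt_ms = x$dt,
                 seed = x$seed, n_spikes_B = nb,
                 n_spikes_A = nrow(x$spikes) - nb)
}
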