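#' One stochastic Heun step of the network (reference implementation)
#'
#' Predictor-corrector update with additive Gaussian white noise on the
#' membrane-potential equations only. The same Wiener increment enters the
#' predictor and the corrector, as required for additive noise; with zero
#' noise the scheme is the deterministic Heun (RK2) method. This pure-R step
#' is the reference against which the compiled integrator core is verified.
#'
#' @param state A `somnox_state`.
#' @param t Time (ms).
#' @param dt Step (ms), > 0.
#' @param config A [network_config()].
#' @param increments Optional list with `dW_A` (length N) and `dW_B`
#'   (scalar): Wiener increments distributed N(0, dt). They are scaled
#'   internally by `sqrt(2 D) / C_m` per the noise convention
#'   \eqn{\langle\xi\xi'\rangle = 2D\delta}. Default: zero increments.
#' @return The updated `somnox_state`.
#' @export
heun_step <- function(state, t, dt, config, increments = NULL) {
  stopifnot(dt > 0)
  N <- config$N
  p <- config$params
  eta <- numeric(state_dim(config))
  if (!is.null(increments)) {
    if (!is.null(increments$dW_A))
      eta[seq_len(N)] <- sqrt(2 * config$noise$D_A) * increments$dW_A / p$C_m
    if (!is.null(increments$dW_B))
      eta[5 * N + length(state$a_glAB) + 1] <-
        sqrt(2 * config$noise$D_B) * increments$dW_B / p$C_m
  }
  y <- pack_state(state)
  f1 <- pack_state(derivatives(state, t, config))
  y_pred <- y + dt * f1 + eta
  f2 <- pack_state(derivatives(unpack_somnox(y_pred, config), t + dt, config))
  y_new <- y + dt / 2 * (f1 + f2) + eta
  gi <- (4 * N + 1):(5 * N)
  y_new[gi] <- pmin(pmax(y_new[gi], 0), 1)
  out <- unpack_somnox(y_new, config)
  if (any(!is.finite(y_new))) {
    bad <- names_flat_state(config)[which(!is.finite(y_new))[1]]
    stop("non-finite state after Heun step (first offending variable: ",
         bad, ")")
  }
  out
}

# unpack without the [0,1] construction checks (predictor states may poke
# slightly outside)
unpack_somnox <- function(y, config) {
  N <- config$N
  M <- length(config$thresholds_AB)
  idx <- function(k) y[((k - 1) * N + 1):(k * N)]
  structure(list(V_A = idx(1), aK_A = idx(2), a_glBA = idx(3), a_ox = idx(4),
                 g_ox_avail = idx(5), a_glAB = y[(5 * N + 1):(5 * N + M)],
                 V_B = y[5 * N + M + 1], aK_B = y[5 * N + M + 2]),
            class = "somnox_state")
}

names_flat_state <- function(config) {
  N <- config$N
  M <- length(config$thresholds_AB)
  c(paste0("V_A", seq_len(N)), paste0("aK_A", seq_len(N)),
    paste0("a_glBA", seq_len(N)), paste0("a_ox", seq_len(N)),
    paste0("g_ox_avail", seq_len(N)), paste0("a_glAB", seq_len(M)),
    "V_B", "aK_B")
}

#' Generic scalar stochastic Heun integrator
#'
#' Minimal scalar version of the same predictor-corrector scheme, used to
#' validate the integration order and the noise convention on systems with
#' known closed-form behaviour (exponential decay, Ornstein-Uhlenbeck).
#' The noise term is `sqrt(2 * D)` times a standard Wiener increment.
#'
#' @param drift Function `f(y, t)` giving the deterministic derivative.
#' @param y0 Initial value.
#' @param t0 Initial time.
#' @param dt Step, > 0.
#' @param n_steps Number of steps.
#' @param D Noise intensity under the `2 D delta` autocorrelation convention.
#' @param keep_path If `TRUE` return the whole trajectory, else the final
#'   value.
#' @return Numeric vector (trajectory of length `n_steps + 1`) or scalar.
#' @export
heun_sde <- function(drift, y0, t0 = 0, dt, n_steps, D = 0,
                     keep_path = FALSE) {
  stopifnot(dt > 0, n_steps >= 1)
  y <- y0
  t <- t0
  path <- if (keep_path) numeric(n_steps + 1) else NULL
  if (keep_path) path[1] <- y0
  sd_eta <- sqrt(2 * D * dt)
  for (k in seq_len(n_steps)) {
    eta <- if (D > 0) stats::rnorm(1, sd = sd_eta) else 0
    f1 <- drift(y, t)
    yp <- y + dt * f1 + eta
    y <- y + dt / 2 * (f1 + drift(yp, t + dt)) + eta
    t <- t0 + k * dt
    if (keep_path) path[k + 1] <- y
  }
  if (keep_path) path else y
}

#' Run a network simulation
#'
#' Integrates the network from the silent state (or a supplied state) with
#' the compiled stochastic Heun core, detecting spikes online as upward
#' threshold crossings with a refractory period, and optionally recording
#' down-sampled traces of `V_B`, `V_A1`, and the population means of orexin
#' availability and activation.
#'
#' @param config A [network_config()].
#' @param duration Total simulated time (ms); default `n_periods` stimulus
#'   periods.
#' @param n_periods Convenience alternative to `duration`.
#' @param dt Integration step (ms); must satisfy `dt <= tau_K / 10` so the
#'   fastest activation time constant is resolved. Default 0.1 ms.
#' @param seed Integer seed controlling all noise draws (ignored for
#'   noiseless configurations apart from being echoed).
#' @param init_state Optional `somnox_state` to start from.
#' @param t0 Start time (ms); the stimulus phase is absolute, so starting at
#'   `t0 = k * period` reproduces the periodic drive exactly.
#' @param record_traces Record down-sampled traces (default `TRUE`).
#' @param record_every Trace sampling interval (ms), default 1.
#' @param spike_threshold Spike detection threshold (mV), default 0.
#' @param refractory Spike detection refractory period (ms), default 2.
#' @return An object of class `somnox_sim` with elements `spikes` (tibble:
#'   `neuron_id`, `t_ms`), `spike_times` (named list of numeric vectors),
#'   `traces` (tibble or `NULL`), `final_state`, `dt`, `t0`, `duration`,
#'   `seed`, and `config` (configuration echo).
#' @export
#' @examples
#' cfg <- network_config(N = 2, stimulus = stimulus_spec(enabled = FALSE))
#' sim <- run_simulation(cfg, duration = 500, dt = 0.2)
#' nrow(sim$spikes) # 0: silent without input
run_simulation <- function(config, duration = NULL, n_periods = NULL,
                           dt = 0.1, seed = 1L, init_state = NULL, t0 = 0,
                           record_traces = TRUE, record_every = 1,
                           spike_threshold = 0, refractory = 2) {
  stopifnot(inherits(config, "somnox_config"))
  if (is.null(duration)) {
    if (is.null(n_periods)) stop("supply duration or n_periods")
    duration <- n_periods * config$stimulus$period
  }
  stopifnot(duration > 0)
  if (dt > config$params$tau_K / 10 + 1e-12)
    stop("dt must not exceed tau_K / 10 = ",
         config$params$tau_K / 10, " ms")
  if (is.null(init_state)) init_state <- initial_silent_state(config)
  y0 <- pack_state(init_state)
  n_steps <- round(duration / dt)

  res <- withr::with_seed(as.integer(seed),
    simulate_network_cpp(
      y0, unclass(config$params),
      config$thresholds_BA, config$thresholds_AB,
      as.integer(config$ab_presyn) - 1L,
      config$stimulus$delta_I, config$stimulus$delta_T,
      config$stimulus$period, config$stimulus$enabled,
      config$noise$D_A, config$noise$D_B,
      t0, dt, n_steps, record_every,
      spike_threshold, refractory, record_traces))

  spike_times <- res$spikes
  spikes <- tibble::tibble(
    neuron_id = rep(names(spike_times), lengths(spike_times)),
    t_ms = unlist(spike_times, use.names = FALSE)
  )
  structure(list(
    spikes = spikes,
    spike_times = spike_times,
    traces = if (record_traces) tibble::as_tibble(res$traces) else NULL,
    final_state = unpack_somnox(res$state, config),
    dt = dt, t0 = t0, duration = duration, seed = as.integer(seed),
    spike_threshold = spike_threshold, refractory = refractory,
    config = config
  ), class = "somnox_sim")
}

#' @export
print.somnox_sim <- function(x, ...) {
  cat("<somnox simulation>\n")
  cat(sprintf("  %g ms at dt = %g ms (seed %d); N = %d A neurons + B\n",
              x$duration, x$dt, x$seed, x$config$N))
  nb <- length(x$spike_times[["B"]])
  na <- nrow(x$spikes) - nb
  cat(sprintf("  spikes: %d on B, %d on A neurons\n", nb, na))
  invisible(x)
}
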