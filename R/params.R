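#' Model parameters for one neuron class plus coupling constants
#'
#' Builds the full constant set of the conductance-based sleep-wake network:
#' membrane and ionic-current constants shared by the orexin (A) neurons and
#' the glutamate interneuron (B), the glutamate and orexin synaptic constants,
#' the orexin-availability homeostat, the gap-junction coupling among A
#' neurons, and the rescaled daily period.
#'
#' Units follow the usual conductance-based conventions: voltages in mV,
#' conductances in mS/cm^2, capacitance in uF/cm^2, currents in uA/cm^2,
#' times in ms. The day is rescaled so that `T_day = 24000` ms of model time
#' stands for `T_day_phys = 24` h of physiological time; only the slow orexin
#' constants (`tau_ox`, `theta_dep`, `theta_rec`) participate in the
#' rescaling, the spiking time scales are left untouched.
#'
#' @param ... Named overrides of any default constant (see Details).
#'
#' @details Defaults, chosen so that an uncoupled neuron is silent at rest
#' and fires tonically under depolarization, the reciprocal A-B excitation is
#' self-sustaining only while the orexin gate is open (so that orexin
#' depletion, not glutamate, terminates the wake episode), and a circadian
#' pulse close to the critical height yields the double-periodic response
#' from which the disorder studies start:
#' membrane `C_m = 1`; leak `g_L = 0.1`, `V_L = -60`; sodium `g_Na = 1.5`,
#' `V_Na = 50`, `s_Na = 0.25`, `Vh_Na = -25` (instantaneous activation);
#' potassium `g_K = 2`, `V_K = -90`, `s_K = 0.25`, `Vh_K = -25`, `tau_K = 2`;
#' glutamate `g_gl = 0.12`, `V_gl = 50`, `s_gl = 0.25`,
#' `theta_gl_mean = -30`, `tau_gl = 10`; orexin `g_ox = 0.3`, `V_ox = 50`,
#' `s_ox = 0.5`, `theta_ox = -45`, `tau_ox = 500`; availability gate
#' `g_crit = 0.8` with smooth-gate steepness `gate_k = 40`; homeostat
#' `theta_dep = 10000` (pre-calibration starting point; see
#' [calibrate_orexin_timescales()]), `theta_rec = 10000`; gap junctions
#' `g_gap = 0.1`; day `T_day = 24000` ms, `T_day_phys = 24` h.
#'
#' @return A named list of class `somnox_params`.
#' @export
#' @examples
#' p <- model_params(theta_dep = 21000)
#' p$theta_dep
model_params <- function(...) {
  p <- list(
    C_m = 1,
    g_L = 0.1, V_L = -60,
    g_Na = 1.5, V_Na = 50, s_Na = 0.25, Vh_Na = -25,
    g_K = 2, V_K = -90, s_K = 0.25, Vh_K = -25, tau_K = 2,
    g_gl = 0.12, V_gl = 50, s_gl = 0.25, theta_gl_mean = -30, tau_gl = 10,
    g_ox = 0.3, V_ox = 50, s_ox = 0.5, theta_ox = -45, tau_ox = 500,
    g_crit = 0.8, gate_k = 40,
    theta_dep = 10000, theta_rec = 10000,
    g_gap = 0.1,
    T_day = 24000, T_day_phys = 24
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p <- structure(p, class = "somnox_params")
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity of conductances, capacitance and time constants, the
#' ordering of the time scales (`tau_K < tau_gl <= tau_ox` and both orexin
#' homeostat constants of the order of the daily period), `g_crit` inside
#' (0, 1), and the ordering of the equilibrium potentials
#' (`V_K < V_L < 0 < V_Na`, depolarizing `V_gl`, `V_ox`).
#'
#' @param p A `somnox_params` object.
#' @return `p`, invisibly, if valid; otherwise an error naming every
#'   offending field.
#' @export
validate_params <- function(p) {
  problems <- character()
  pos <- c("C_m", "g_L", "g_Na", "g_K", "g_gl", "g_ox",
           "tau_K", "tau_gl", "tau_ox", "theta_dep", "theta_rec",
           "T_day", "T_day_phys", "gate_k")
  for (f in pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      problems <- c(problems, paste0(f, " must be a positive finite number"))
  }
  if (!is.numeric(p$g_gap) || p$g_gap < 0)
    problems <- c(problems, "g_gap must be >= 0")
  if (length(problems) == 0) {
    if (!(p$tau_K < p$tau_gl && p$tau_gl <= p$tau_ox))
      problems <- c(problems, "time-scale ordering tau_K < tau_gl <= tau_ox violated")
    if (!(p$theta_dep > 10 * p$tau_ox && p$theta_rec > 10 * p$tau_ox))
      problems <- c(problems, "theta_dep and theta_rec must be much longer than tau_ox")
    if (!(p$theta_dep < 10 * p$T_day && p$theta_rec < 10 * p$T_day))
      problems <- c(problems, "theta_dep and theta_rec must be of the order of T_day")
    if (!(p$g_crit > 0 && p$g_crit < 1))
      problems <- c(problems, "g_crit must lie in (0, 1)")
    if (!(p$V_K < p$V_L && p$V_L < 0 && p$V_Na > 0))
      problems <- c(problems, "equilibrium potentials must satisfy V_K < V_L < 0 < V_Na")
    if (!(p$V_gl > 0 && p$V_ox > 0))
      problems <- c(problems, "V_gl and V_ox must be depolarizing (> 0)")
    if (!(p$s_Na > 0 && p$s_K > 0 && p$s_gl > 0 && p$s_ox > 0))
      problems <- c(problems, "all sigmoid slopes must be > 0")
  }
  if (length(problems))
    stop("invalid model parameters:\n  ", paste(problems, collapse = "\n  "))
  invisible(p)
}

#' Periodic rectangular circadian pulse specification
#'
#' The circadian drive is idealized as a train of rectangular current pulses
#' of height `delta_I` and length `delta_T`, repeating every `period` ms with
#' onsets at integer multiples of the period. The pulse window is half-open,
#' `[0, delta_T)`. A `waveform` hook is reserved for alternative circadian
#' shapes; only `"rect"` is implemented.
#'
#' @param delta_I Pulse height (uA/cm^2), >= 0.
#' @param delta_T Pulse length (ms), in (0, period).
#' @param period Daily period T (ms).
#' @param enabled If `FALSE` the drive is identically zero.
#' @param waveform Waveform name; only `"rect"` is available.
#' @return A list of class `somnox_stimulus`.
#' @export
stimulus_spec <- function(delta_I = 2, delta_T = 1000, period = 24000,
                          enabled = TRUE, waveform = "rect") {
  waveform <- match.arg(waveform, "rect")
  stopifnot(is.numeric(delta_I), length(delta_I) == 1, delta_I >= 0,
            is.numeric(delta_T), length(delta_T) == 1,
            is.numeric(period), length(period) == 1, period > 0)
  if (!(delta_T > 0 && delta_T < period))
    stop("delta_T must satisfy 0 < delta_T < period")
  structure(list(delta_I = delta_I, delta_T = delta_T, period = period,
                 enabled = isTRUE(enabled), waveform = waveform),
            class = "somnox_stimulus")
}

#' Membrane-current noise specification
#'
#' Zero-mean Gaussian white noise added to the membrane-potential equations
#' by the stochastic integrator, with autocorrelation
#' \eqn{\langle \xi(t)\xi(t')\rangle = 2D\,\delta(t-t')}. `D_A` acts on every
#' A-neuron equation (independent streams), `D_B` on neuron B.
#'
#' @param D_A Noise intensity on each A neuron (uA^2 ms / cm^4), >= 0.
#' @param D_B Noise intensity on neuron B, >= 0.
#' @return A list of class `somnox_noise`.
#' @export
noise_spec <- function(D_A = 0, D_B = 0) {
  stopifnot(is.numeric(D_A), length(D_A) == 1, D_A >= 0,
            is.numeric(D_B), length(D_B) == 1, D_B >= 0)
  structure(list(D_A = D_A, D_B = D_B), class = "somnox_noise")
}

#' Quenched synaptic-threshold diversity specification
#'
#' Describes where quenched disorder lives and how strong it is: the
#' half-activation thresholds of one glutamate synapse family (`"BA"`, the
#' synapses at the A neurons driven by B, or `"AB"`, the synapses at B driven
#' by the A neurons) are drawn once per realization from a bell-shaped
#' density centred at `mean` with dispersion parameter `width`
#' (see [threshold_density()]).
#'
#' @param site One of `"none"`, `"BA"`, `"AB"`.
#' @param mean Centre of the threshold density (mV); `NULL` means "use the
#'   homogeneous `theta_gl_mean` of the model parameters", which keeps the
#'   diversified ensemble mean pinned to the homogeneous model.
#' @param width Dispersion parameter w (mV), >= 0. The standard deviation of
#'   the density is \eqn{(\pi/\sqrt 3)\,w}.
#' @param seed RNG seed used to draw the threshold realization.
#' @return A list of class `somnox_diversity`.
#' @export
diversity_spec <- function(site = c("none", "BA", "AB"), mean = NULL,
                           width = 0, seed = 1L) {
  site <- match.arg(site)
  stopifnot(is.numeric(width), length(width) == 1, width >= 0)
  if (site == "none" && width != 0)
    stop("site = \"none\" requires width = 0")
  structure(list(site = site, mean = mean, width = width,
                 seed = as.integer(seed)),
            class = "somnox_diversity")
}

#' Full network configuration
#'
#' Assembles the N+1-neuron network: `N` orexin (A) neurons all-to-all
#' coupled by gap junctions plus one glutamate interneuron (B), the shared
#' model parameters, the circadian stimulus, the noise intensities, and the
#' quenched threshold diversity. The two glutamate-threshold vectors are
#' materialized here (one draw per configuration, reproducible via the
#' diversity seed); with zero width every entry equals `theta_gl_mean`.
#'
#' @param N Number of A neurons (>= 1). Default 20.
#' @param params A [model_params()] set.
#' @param stimulus A [stimulus_spec()].
#' @param noise A [noise_spec()].
#' @param diversity A [diversity_spec()].
#' @param thresholds_BA,thresholds_AB Optional explicit threshold vectors
#'   (mV, length `N`), overriding the sampled ones — used to replay a stored
#'   realization exactly.
#' @return A list of class `somnox_config` with elements `N`, `params`,
#'   `stimulus`, `noise`, `diversity`, `thresholds_BA`, `thresholds_AB`,
#'   `ab_presyn` (presynaptic A index of each A-to-B synapse).
#' @export
#' @examples
#' cfg <- network_config(N = 5, diversity = diversity_spec("BA", width = 2))
#' cfg$thresholds_BA
network_config <- function(N = 20, params = model_params(),
                           stimulus = stimulus_spec(), noise = noise_spec(),
                           diversity = diversity_spec(),
                           thresholds_BA = NULL, thresholds_AB = NULL) {
  stopifnot(is.numeric(N), length(N) == 1, N >= 1, N == as.integer(N))
  N <- as.integer(N)
  validate_params(params)
  mu <- if (is.null(diversity$mean)) params$theta_gl_mean else diversity$mean
  if (is.null(thresholds_BA)) {
    thresholds_BA <- if (diversity$site == "BA")
      sample_thresholds(N, mu, diversity$width, diversity$seed)
    else rep(params$theta_gl_mean, N)
  }
  if (is.null(thresholds_AB)) {
    thresholds_AB <- if (diversity$site == "AB")
      sample_thresholds(N, mu, diversity$width, diversity$seed + 1L)
    else rep(params$theta_gl_mean, N)
  }
  if (length(thresholds_BA) != N || length(thresholds_AB) != N)
    stop("threshold vectors must have length N = ", N)
  structure(list(N = N, params = params, stimulus = stimulus, noise = noise,
                 diversity = diversity,
                 thresholds_BA = as.numeric(thresholds_BA),
                 thresholds_AB = as.numeric(thresholds_AB),
                 ab_presyn = seq_len(N)),
            class = "somnox_config")
}

#' @export
print.somnox_config <- function(x, ...) {
  cat("<somnox network config>\n")
  cat("  N A-neurons:", x$N, "+ 1 B neuron\n")
  cat(sprintf("  stimulus: delta_I = %.4g uA/cm^2, delta_T = %g ms, T = %g ms%s\n",
              x$stimulus$delta_I, x$stimulus$delta_T, x$stimulus$period,
              if (x$stimulus$enabled) "" else " (disabled)"))
  cat(sprintf("  noise: D_A = %g, D_B = %g\n", x$noise$D_A, x$noise$D_B))
  cat(sprintf("  diversity: site = %s, width = %g mV (seed %d)\n",
              x$diversity$site, x$diversity$width, x$diversity$seed))
  invisible(x)
}
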