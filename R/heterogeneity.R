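#' Bell-shaped threshold density
#'
#' Probability density of the quenched synaptic half-activation thresholds:
#' a logistic-derivative bell,
#' \deqn{p(\theta) = \frac{e^{-(\theta-\bar\theta)/w}}
#'   {w\,(1 + e^{-(\theta-\bar\theta)/w})^2},}
#' symmetric and unimodal about `mean` with standard deviation
#' \eqn{(\pi/\sqrt 3)\,w}. Its cumulative distribution is itself a sigmoid of
#' steepness `1/w`, which is what makes the large-diversity limit of the
#' effective synaptic drive retain the sigmoid form with a reduced slope.
#'
#' @param theta Threshold value(s) (mV); vectorized.
#' @param mean Centre \eqn{\bar\theta} (mV).
#' @param width Dispersion parameter w (mV), > 0.
#' @return Density values (1/mV).
#' @export
threshold_density <- function(theta, mean, width) {
  if (!(is.numeric(width) && length(width) == 1 && width > 0))
    stop("width must be > 0 (width = 0 is a point mass, handled by the sampler)")
  stats::dlogis(theta, location = mean, scale = width)
}

#' Sample quenched thresholds
#'
#' Draws `N` i.i.d. thresholds from [threshold_density()]; with `width = 0`
#' returns `N` copies of `mean` (the homogeneous model). Reproducible for a
#' fixed seed, without disturbing the caller's RNG state.
#'
#' @param N Number of thresholds.
#' @param mean Centre (mV).
#' @param width Dispersion parameter w (mV), >= 0.
#' @param seed Integer RNG seed.
#' @return Numeric vector of `N` thresholds (mV).
#' @export
sample_thresholds <- function(N, mean, width, seed = 1L) {
  stopifnot(N >= 1, width >= 0)
  if (width == 0) return(rep(mean, N))
  withr::with_seed(as.integer(seed),
                   stats::rlogis(N, location = mean, scale = width))
}

#' Effective (diversity-averaged) synaptic equilibrium
#'
#' The population-averaged steady-state activation seen by neuron B when the
#' A-to-B glutamate thresholds are diversified:
#' \deqn{\bar\sigma(V) = \int p(\theta)\,\sigma(V; s, \theta)\, d\theta,}
#' computed by adaptive quadrature. As `width -> 0` this reduces to the
#' homogeneous sigmoid; for `width >> 1/slope` the sigmoid acts as a step
#' and the integral tends to the density's own CDF, i.e. a sigmoid of
#' steepness `1/width`.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param mean Threshold-density centre (mV).
#' @param width Dispersion parameter w (mV), >= 0.
#' @param slope Sigmoid steepness s (1/mV).
#' @return Effective activation fraction in \[0, 1\].
#' @export
effective_equilibrium <- function(V, mean, width, slope) {
  stopifnot(width >= 0, slope > 0)
  if (width == 0) return(sigmoid_activation(V, slope, mean))
  # substitute theta = mean + width * qlogis(u): the density becomes the
  # uniform measure on (0, 1), so the quadrature stays well conditioned for
  # arbitrarily small (or large) widths
  vapply(V, function(v) {
    r <- stats::integrate(
      function(u) sigmoid_activation(v, slope,
                                     mean + width * stats::qlogis(u)),
      lower = 0, upper = 1, abs.tol = 1e-9, rel.tol = 1e-9,
      stop.on.error = FALSE)
    if (r$message != "OK" && r$abs.error > 1e-6)
      stop("quadrature failed to converge: ", r$message)
    min(max(r$value, 0), 1)
  }, numeric(1))
}

#' Fitted effective sigmoid steepness
#'
#' Least-squares fit of a single sigmoid (centre fixed at `mean`) to the
#' diversity-averaged equilibrium over `V` in `mean +/- (20 + 5*width)` mV.
#' The fitted steepness decreases monotonically from `slope` (no diversity)
#' towards `1/width` (diversity-dominated limit).
#'
#' @param width Dispersion parameter w (mV), >= 0.
#' @param slope Bare sigmoid steepness s (1/mV).
#' @param mean Centre (mV); the fit is translation invariant.
#' @return Fitted effective steepness (1/mV).
#' @export
fit_effective_slope <- function(width, slope, mean = 0) {
  stopifnot(width >= 0, slope > 0)
  if (width == 0) return(slope)
  half_range <- 20 + 5 * width
  V <- seq(mean - half_range, mean + half_range, length.out = 201)
  y <- effective_equilibrium(V, mean, width, slope)
  loss <- function(s_eff) sum((sigmoid_activation(V, s_eff, mean) - y)^2)
  fit <- stats::optimize(loss, interval = c(1e-6, slope * 1.5))
  if (!is.finite(fit$objective)) stop("effective-slope fit failed")
  fit$minimum
}

#' Exact two-neuron reduction for A-to-B threshold diversity
#'
#' When diversity lives only in the A-to-B glutamate thresholds, with
#' homogeneous B-to-A synapses and no noise on the A neurons, all A neurons
#' follow identical trajectories and the network reduces exactly to a
#' two-neuron model in which neuron B is driven by the finite-N mixture
#' \eqn{(1/N)\sum_i \sigma(V_A; s, \theta_i)}. The reduction is exact (not an
#' approximation) because the synaptic activation equations are linear in the
#' activation with a common time constant. The returned configuration keeps
#' one A neuron but all N A-to-B synaptic thresholds, each fed by that
#' neuron.
#'
#' @param config A [network_config()] with `diversity$site == "AB"`, zero
#'   A-neuron noise, and homogeneous B-to-A thresholds.
#' @return A `somnox_config` with `N = 1`.
#' @export
effective_two_neuron_config <- function(config) {
  stopifnot(inherits(config, "somnox_config"))
  if (config$noise$D_A != 0)
    stop("reduction requires zero noise on the A neurons")
  if (length(unique(config$thresholds_BA)) != 1)
    stop("reduction requires homogeneous B-to-A thresholds")
  if (!(config$diversity$site %in% c("AB", "none")))
    stop("reduction applies to diversity at the A-to-B synapses only")
  out <- config
  out$N <- 1L
  out$thresholds_BA <- config$thresholds_BA[1]
  out$thresholds_AB <- config$thresholds_AB   # full mixture retained
  out$ab_presyn <- rep(1L, length(config$thresholds_AB))
  out
}
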