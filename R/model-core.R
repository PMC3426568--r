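#' Sigmoid activation function
#'
#' The voltage-dependent steady-state activation
#' \eqn{\sigma(V) = 1 / (1 + e^{-s (V - V_h)})} used throughout the model for
#' ionic-current activation, presynaptic spike detection and the orexin
#' availability gate.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param slope Steepness s (1/mV), > 0.
#' @param half_potential Half-activation potential V_h (mV).
#' @return Activation fraction in \[0, 1\], strictly increasing in `V`.
#' @export
#' @examples
#' sigmoid_activation(-25, 0.25, -25) # 0.5
sigmoid_activation <- function(V, slope, half_potential) {
  if (any(!is.finite(V))) stop("non-finite membrane potential")
  stopifnot(slope > 0)
  1 / (1 + exp(-slope * (V - half_potential)))
}

#' Ionic and synaptic currents
#'
#' Evaluates one current term \eqn{I = g\,a\,(V_{post} - V_{eq})} with the
#' conductance/equilibrium pair selected by `kind`. The leak takes
#' activation 1; the sodium current is activated instantaneously by its own
#' voltage sigmoid, so its `activation` argument is ignored.
#'
#' @param kind One of `"L"`, `"Na"`, `"K"`, `"gl"`, `"ox"`.
#' @param V_post Postsynaptic (or own) membrane potential (mV).
#' @param activation Activation fraction in \[0, 1\] (ignored for `"L"` and
#'   `"Na"`).
#' @param params A [model_params()] set.
#' @return Current in uA/cm^2 (positive = outward under the sign convention
#'   of the membrane equation, where currents enter with a minus sign).
#' @export
ionic_current <- function(kind, V_post, activation = 1, params = model_params()) {
  kind <- match.arg(kind, c("L", "Na", "K", "gl", "ox"))
  if (kind %in% c("K", "gl", "ox") &&
      any(activation < 0 | activation > 1))
    stop("activation must lie in [0, 1]")
  p <- params
  switch(kind,
    L  = p$g_L * (V_post - p$V_L),
    Na = p$g_Na * sigmoid_activation(V_post, p$s_Na, p$Vh_Na) * (V_post - p$V_Na),
    K  = p$g_K * activation * (V_post - p$V_K),
    gl = p$g_gl * activation * (V_post - p$V_gl),
    ox = p$g_ox * activation * (V_post - p$V_ox)
  )
}

# ---- network state ---------------------------------------------------------

state_dim <- function(config) 5L * config$N + length(config$thresholds_AB) + 2L

#' Construct a network state
#'
#' @param V_A,aK_A,a_glBA,a_ox,g_ox_avail Length-N vectors: A-neuron membrane
#'   potentials (mV), potassium activations, B-to-A glutamate activations,
#'   orexin-current activations, and orexin availabilities.
#' @param a_glAB A-to-B glutamate synaptic activations (one per synapse;
#'   length N in the full model).
#' @param V_B,aK_B Neuron-B membrane potential (mV) and potassium activation.
#' @return A list of class `somnox_state`.
#' @export
network_state <- function(V_A, aK_A, a_glBA, a_ox, g_ox_avail, a_glAB,
                          V_B, aK_B) {
  N <- length(V_A)
  if (N < 1) stop("need at least one A neuron")
  lens <- lengths(list(aK_A, a_glBA, a_ox, g_ox_avail))
  if (any(lens != N)) stop("per-A-neuron state vectors must all have length N")
  acts <- c(aK_A, a_glBA, a_ox, g_ox_avail, a_glAB, aK_B)
  if (any(acts < 0 | acts > 1))
    stop("activation variables and availabilities must lie in [0, 1]")
  structure(list(V_A = as.numeric(V_A), aK_A = as.numeric(aK_A),
                 a_glBA = as.numeric(a_glBA), a_ox = as.numeric(a_ox),
                 g_ox_avail = as.numeric(g_ox_avail),
                 a_glAB = as.numeric(a_glAB),
                 V_B = as.numeric(V_B), aK_B = as.numeric(aK_B)),
            class = "somnox_state")
}

#' Flatten a state to the integrator layout
#'
#' Layout: `V_A[N], aK_A[N], a_glBA[N], a_ox[N], g_ox_avail[N], a_glAB[M],
#' V_B, aK_B`.
#' @param state A `somnox_state`.
#' @return A numeric vector.
#' @export
pack_state <- function(state) {
  c(state$V_A, state$aK_A, state$a_glBA, state$a_ox, state$g_ox_avail,
    state$a_glAB, state$V_B, state$aK_B)
}

#' Rebuild a `somnox_state` from the flat integrator layout
#' @param y Numeric vector in the layout of [pack_state()].
#' @param N Number of A neurons.
#' @param M Number of A-to-B synapses (defaults to `N`).
#' @return A `somnox_state`.
#' @export
unpack_state <- function(y, N, M = N) {
  if (length(y) != 5 * N + M + 2)
    stop("flat state has wrong length")
  idx <- function(k) y[((k - 1) * N + 1):(k * N)]
  structure(list(V_A = idx(1), aK_A = idx(2), a_glBA = idx(3), a_ox = idx(4),
                 g_ox_avail = idx(5),
                 a_glAB = y[(5 * N + 1):(5 * N + M)],
                 V_B = y[5 * N + M + 1], aK_B = y[5 * N + M + 2]),
            class = "somnox_state")
}

#' Deterministic right-hand side of the network equations
#'
#' Pure-R reference implementation of the coupled membrane/activation/orexin
#' equations; the compiled integrator core evaluates the same system. Each A
#' neuron obeys a conductance-based membrane equation with leak, sodium
#' (instantaneous), potassium (first-order activation), the glutamate current
#' from B, all-to-all gap-junction coupling, and the external circadian
#' pulse. Neuron B receives the population means of the A-to-B glutamate and
#' orexin currents. The orexin activation is gated by availability, which
#' depletes while its neuron fires (time constant `theta_dep`) and recovers
#' during silence (`theta_rec`). Noise is not part of the deterministic RHS;
#' it is added by the stochastic integrator.
#'
#' @param state A `somnox_state` satisfying its invariants.
#' @param t Time (ms).
#' @param config A [network_config()].
#' @return A `somnox_state`-shaped list of time derivatives.
#' @export
derivatives <- function(state, t, config) {
  p <- config$params
  N <- config$N
  if (length(state$V_A) != N || length(config$thresholds_BA) != N)
    stop("state/config vector lengths do not match N")
  M <- length(state$a_glAB)
  V_A <- state$V_A; V_B <- state$V_B

  sig <- sigmoid_activation
  I_ext <- pulse_current(t, config$stimulus)

  I_L <- p$g_L * (V_A - p$V_L)
  I_Na <- p$g_Na * sig(V_A, p$s_Na, p$Vh_Na) * (V_A - p$V_Na)
  I_K <- p$g_K * state$aK_A * (V_A - p$V_K)
  I_gl <- p$g_gl * state$a_glBA * (V_A - p$V_gl)
  # pairwise differences: exact cancellation for synchronized neurons
  I_gap <- p$g_gap * rowSums(outer(V_A, V_A, "-"))
  dV_A <- (-I_L - I_Na - I_K - I_gl - I_gap + I_ext) / p$C_m

  daK_A <- (sig(V_A, p$s_K, p$Vh_K) - state$aK_A) / p$tau_K
  da_glBA <- (sig(V_B, p$s_gl, config$thresholds_BA) - state$a_glBA) / p$tau_gl

  fire <- sig(V_A, p$s_ox, p$theta_ox)
  gate <- sig(state$g_ox_avail, p$gate_k, p$g_crit)
  da_ox <- (gate * fire - state$a_ox) / p$tau_ox
  dg <- (1 - state$g_ox_avail) / p$theta_rec - fire * state$g_ox_avail / p$theta_dep

  da_glAB <- (sig(V_A[config$ab_presyn], p$s_gl, config$thresholds_AB) -
                state$a_glAB) / p$tau_gl

  # offset-form means: exact when all entries coincide (N-reduction contract)
  mean_off <- function(a) a[1] + sum(a - a[1]) / length(a)
  I_LB <- p$g_L * (V_B - p$V_L)
  I_NaB <- p$g_Na * sig(V_B, p$s_Na, p$Vh_Na) * (V_B - p$V_Na)
  I_KB <- p$g_K * state$aK_B * (V_B - p$V_K)
  I_glB <- p$g_gl * mean_off(state$a_glAB) * (V_B - p$V_gl)
  I_oxB <- p$g_ox * mean_off(state$a_ox) * (V_B - p$V_ox)
  dV_B <- (-I_LB - I_NaB - I_KB - I_glB - I_oxB) / p$C_m
  daK_B <- (sig(V_B, p$s_K, p$Vh_K) - state$aK_B) / p$tau_K

  structure(list(V_A = dV_A, aK_A = daK_A, a_glBA = da_glBA, a_ox = da_ox,
                 g_ox_avail = dg, a_glAB = da_glAB, V_B = dV_B, aK_B = daK_B),
            class = "somnox_state_deriv")
}

#' Resting membrane potential of an uncoupled neuron
#'
#' Locates, by root finding, the silent fixed point of the single-neuron
#' membrane equation with potassium activation at equilibrium and no
#' synaptic or external input.
#'
#' @param params A [model_params()] set.
#' @return Resting potential (mV).
#' @export
resting_potential <- function(params = model_params()) {
  p <- params
  f <- function(V) {
    -p$g_L * (V - p$V_L) -
      p$g_Na * sigmoid_activation(V, p$s_Na, p$Vh_Na) * (V - p$V_Na) -
      p$g_K * sigmoid_activation(V, p$s_K, p$Vh_K) * (V - p$V_K)
  }
  stats::uniroot(f, lower = p$V_K, upper = -20, tol = 1e-12)$root
}

#' Silent initial state
#'
#' The network's silent rest point with orexin availability fully recovered
#' (`g_ox_avail = 1`): every membrane potential at its self-consistent
#' resting value (including the weak resting synaptic currents) and every
#' activation at its corresponding equilibrium. Located by Gauss-Seidel
#' fixed-point iteration with per-neuron scalar root finding; with
#' homogeneous thresholds all A neurons are identical.
#'
#' @param config A [network_config()].
#' @return A `somnox_state`.
#' @export
initial_silent_state <- function(config) {
  p <- config$params
  N <- config$N
  sig <- sigmoid_activation
  gate1 <- sig(1, p$gate_k, p$g_crit)
  V_A <- V_B <- resting_potential(p)

  # identical A neurons (gap currents cancel); the weak resting synaptic
  # feedback uses the threshold-ensemble mean drive
  balance <- function(V, a_gl, a_ox = 0) {
    -p$g_L * (V - p$V_L) -
      p$g_Na * sig(V, p$s_Na, p$Vh_Na) * (V - p$V_Na) -
      p$g_K * sig(V, p$s_K, p$Vh_K) * (V - p$V_K) -
      p$g_gl * a_gl * (V - p$V_gl) -
      p$g_ox * a_ox * (V - p$V_ox)
  }
  for (iter in 1:100) {
    V_old <- c(V_A, V_B)
    V_A <- stats::uniroot(balance, c(p$V_K, -20), tol = 1e-13,
                          a_gl = mean(sig(V_B, p$s_gl,
                                          config$thresholds_BA)))$root
    V_B <- stats::uniroot(balance, c(p$V_K, -20), tol = 1e-13,
                          a_gl = mean(sig(V_A, p$s_gl,
                                          config$thresholds_AB)),
                          a_ox = gate1 * sig(V_A, p$s_ox, p$theta_ox))$root
    if (max(abs(c(V_A, V_B) - V_old)) < 1e-12) break
  }
  network_state(
    V_A = rep(V_A, N),
    aK_A = rep(sig(V_A, p$s_K, p$Vh_K), N),
    a_glBA = sig(V_B, p$s_gl, config$thresholds_BA),
    a_ox = rep(gate1 * sig(V_A, p$s_ox, p$theta_ox), N),
    g_ox_avail = rep(1, N),
    a_glAB = sig(V_A, p$s_gl, config$thresholds_AB),
    V_B = V_B, aK_B = sig(V_B, p$s_K, p$Vh_K)
  )
}
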