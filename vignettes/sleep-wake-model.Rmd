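---
title: "A heterogeneous orexin-neuron model of the sleep-wake cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A heterogeneous orexin-neuron model of the sleep-wake cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`somnox` simulates a minimal conductance-based network for the homeostatic
regulation of the sleep-wake cycle: `N` orexin (hypocretin) neurons
(`A_1 ... A_N`), all-to-all coupled by gap junctions, reciprocally connected
to a single glutamate interneuron (`B`). Wake is identified with tonic
(periodic single-spike) firing of the pair, sleep with silence.

Each neuron carries a two-variable spiking skeleton — membrane potential
with instantaneous sodium activation, leak, and a first-order potassium
activation,

$$C_m \dot V = -g_L(V - V_L) - g_{Na}\,\sigma_{Na}(V)(V - V_{Na})
  - g_K\,a_K\,(V - V_K) - I_{syn} + I_{ext}(t) + \xi(t),$$
$$\tau_K \dot a_K = \sigma_K(V) - a_K,
  \qquad \sigma_x(V) = \frac{1}{1 + e^{-s_x (V - V_{h,x})}},$$

which is silent at rest and fires tonically under sustained depolarization.

Three synaptic pathways close the loop:

* **B → A glutamate**: each `A_i` receives
  `g_gl a_glBA,i (V_i - V_gl)`, with
  `tau_gl * da/dt = sigma(V_B; s_gl, theta_i^BA) - a` — presynaptic drive
  from the *other* neuron.
* **A → B glutamate**: `B` receives the population mean of the analogous
  activations driven by each `V_{A,i}` through thresholds `theta_i^AB`.
* **A → B orexin**: `B` also receives the mean orexin current
  `g_ox a_ox,i (V_B - V_ox)`, with
  `tau_ox * da_ox/dt = H(g_i) sigma(V_A; s_ox, theta_ox) - a_ox`.

The homeostat is the per-neuron orexin availability `g_i in [0, 1]`:

$$\dot g_i = \frac{1 - g_i}{\theta_{rec}}
  - \sigma(V_{A,i}; s_{ox}, \theta_{ox})\,\frac{g_i}{\theta_{dep}},$$

depleted while its neuron fires and recovered during silence. The gate
`H(g) = sigma(g; gate_k, g_crit)` is a smooth version of "enough orexin
above a critical threshold": we keep the right-hand side C^1 for the
integrator; the Heaviside step is the limiting alternative.

The circadian input is an idealized train of rectangular current pulses
(height `delta_I`, length `delta_T`, period `T_day`) applied identically to
all A neurons; the waveform slot is extensible but only the rectangular
train is implemented.

The whole system is an excitable feedback loop: the pulse ignites firing in
the A population, reciprocal excitation (with the orexin pathway
load-bearing) maintains it after the pulse ends, and wake terminates when
availability falls low enough that the orexin current collapses — sleep
pressure in the sense of the two-process picture, carried entirely by `g`.

## Parameters, units and how the defaults were chosen

All voltages are in mV, times in ms, currents in uA/cm^2, conductances in
mS/cm^2. Positive external current depolarizes. The day is rescaled:
`T_day = 24000` ms of model time stands for 24 h, so "16 hours of
wakefulness" is a 16 s wake episode. Only the slow orexin constants
(`tau_ox`, `theta_dep`, `theta_rec`) take part in that rescaling; the
spiking time scales (`tau_K = 2` ms, `tau_gl = 10` ms) are left alone, and
`rescale_day()` lets you shrink the day further (the test suite uses an
8 s day) by the same argument: the results only depend on the ordering
`tau_K < tau_gl << tau_ox << theta_dep, theta_rec ~ T_day`.

The spiking skeleton (`g_L = 0.1`, `V_L = -60`; `g_Na = 1.5`, `V_Na = 50`,
`s_Na = 0.25`, `Vh_Na = -25`; `g_K = 2`, `V_K = -90`, `s_K = 0.25`,
`Vh_K = -25`, `tau_K = 2`) is a standard simplified Hodgkin-Huxley
parameterization: silent at rest near -60 mV, tonic above a rheobase of
order 1 uA/cm^2.

The coupling constants were fixed by three qualitative requirements that
the architecture imposes, in this order:

1. **Orexin must be load-bearing.** If the glutamate loop alone
   (A → B → A) can sustain tonic firing, sleep never initiates. With the
   synaptic activations averaging ~0.1 during tonic firing, this bounds
   `g_gl` from above; `g_gl = 0.12` makes the glutamate-only loop
   subcritical while glutamate plus orexin is robustly supercritical.
2. **Depletion must win against recovery during wake.** The availability
   ODE's recovery term bounds the wake-state asymptote of `g` at
   `g_inf ~ theta_dep / (theta_dep + fire * theta_rec)` (with `fire` the
   wake-time average of the firing sigmoid). The critical threshold has to
   sit just above that asymptote or the gate never closes; this is why
   `g_crit = 0.8` is high, with a fairly sharp gate (`gate_k = 40`) so the
   orexin current collapses decisively once `g` crosses it.
3. **Ignition must depend on the slow state.** The firing sigmoid
   (`theta_ox = -45`, `s_ox = 0.5`) separates tonic firing (average ~0.3)
   from rest (~6e-4) without acting as a subthreshold amplifier; with a
   shallower sigmoid the sleeping network amplifies arbitrarily small
   pulses through the orexin pathway and the critical pulse height loses
   its meaning.

`theta_dep = 10000` ms is only a starting point: the shipped calibration
(`calibrate_orexin_timescales()`) tunes it until the mean wake episode
matches the target wake fraction (default 2/3, i.e. 16 s of a 24 s day)
within a 3% tolerance. Wake duration grows monotonically with `theta_dep`
along the regular branch, but that branch ends: at larger depletion
constants the period-return map destabilizes into period-doubled and then
permanently-awake regimes whose *mean* wake can also cross the target. The
calibration therefore scans `theta_dep` geometrically, accepts a candidate
only when the settled tail of the per-period episodes is regular (spread
at most a quarter of the mean over the last six periods — the first
retained periods still carry a damped alternation), bisects inside a
regular straddle of the target when one exists, and otherwise refines
locally around the best regular candidate. If the calibrated cycle failed
to sustain single-periodicity the routine would strengthen overnight
recovery by reducing `theta_rec` in 10% steps; with the shipped defaults
this never triggers.

## The reference state and the critical pulse height

`find_pulse_threshold()` bisects `delta_I` for the onset of the regular
cycle: a height succeeds when the first period carries a sustained wake
episode *and* the response stays single-periodic over six periods. Just
below that onset the model shows the characteristic double-periodic
response — the prolonged wake state appears only every other day, because
after a full wake day the availability has not recovered enough for the
(slightly sub-critical) pulse to ignite the loop, while after a skipped day
it has. `make_reference_config()` scans factors just below 1 (0.99 ... 0.93
times the critical height) and returns the first double-periodic
configuration; this deliberately non-optimal, maximally sensitive state is
the starting point of every disorder experiment. Below the double-periodic
window the pulse never ignites from the silent state at all — the
operating order is: silence, then period-2, then period-1 as `delta_I`
grows.

## Quantifying cycle quality

Wake is reconstructed from neuron B's spike train by the interval rule:
each spike extends wakefulness until the next spike or for at most `gap`
ms. Tonic firing (inter-spike intervals of tens of ms) yields one
contiguous episode; an isolated spike contributes a `gap`-long awakening.
`gap = 150` ms was chosen well above tonic inter-spike intervals and well
below the day/night windows; it also keeps the canonical all-day-tonic
fixture within 0.02 of `Q = 1`, since the only edge effect is the single
extension spilling past the last spike.

Each period splits into a day window (first fraction `f_w = 2/3`) and the
complementary night window, and

$$Q = \frac{\langle W_d \rangle}{f_w T} -
      \frac{\langle W_n \rangle}{(1 - f_w) T} \in [-1, 1],$$

mean day-wake fraction minus mean night-wake fraction: 1 for
wake-all-day/sleep-all-night, 0 for total silence, negative when night
wake dominates. The first simulated period is discarded as transient by
default. Periodicity is classified from the per-period day-wake times
(wake day = at least a quarter of the day window): all wake days is
`period1`, strict alternation `period2`, anything else `irregular`.

`synthetic_spike_train()` generates day/night-structured trains (tonic
spikes inside prescribed windows, optional jitter) so the whole metric
layer is testable without the simulator, including against a brute-force
1-ms occupancy oracle.

## Disorder: noise and quenched diversity

Membrane noise is zero-mean Gaussian and white, entering only the voltage
equations, with the `2 D delta(t - t')` autocorrelation convention — an
Ornstein-Uhlenbeck process integrated by the same scheme has stationary
variance `D * tau`, which the tests verify.

Quenched diversity lives in the glutamate half-activation thresholds,
drawn once per realization from a logistic (bell-shaped) density centred
on the homogeneous value with dispersion parameter `w` (standard deviation
`pi w / sqrt(3)`). The logistic choice has the property that the
population-averaged synaptic drive keeps the sigmoid form in both limits:
as `w -> 0` it is the bare sigmoid (steepness `s`), and for `w >> 1/s` it
tends to the density's own CDF — again a sigmoid, of steepness `1/w`.
`fit_effective_slope()` confirms the same form holds in between with a
monotonically decreasing effective steepness; note the convolution adds
scales roughly in quadrature (`sqrt(w^2 + 1/s^2)`), so the fitted slope
slightly undershoots `1/w` at finite width.

Diversity at the A→B synapses leaves all A neurons identical, so the
network reduces *exactly* to a two-neuron model whose B-drive equilibrium
is the finite-N threshold mixture — exact because the activation ODEs are
linear in the activation with a common time constant;
`effective_two_neuron_config()` implements the reduction and the tests
assert trace-level agreement. Diversity at the B→A synapses is the truly
heterogeneous case: neurons with low thresholds respond earlier to the
pulse and pull the rest along through the gap junctions. At an
intermediate width this converts the double-periodic reference into a
regular every-day cycle (diversity-induced resonance); at large widths
some synapses are tonically active and the cycle degrades again. Noise on
neuron B shows the analogous but milder stochastic resonance, with
isolated night spikes at high intensity; noise on the A population mainly
lengthens wake episodes at large intensities because the gap coupling
keeps the population coherent.

## Numerical scheme

The integrator is the stochastic Heun (predictor-corrector) method:
second order for the deterministic part, with the *same* Wiener increment
(`N(0, dt)`, scaled by `sqrt(2 D)/C_m`) entering predictor and corrector,
as appropriate for additive noise. The hot loop is compiled (Rcpp) and is
verified against a pure-R reference step both noiselessly (exact) and with
matched RNG streams (exact given the same draws). Default `dt = 0.1` ms
resolves the fastest time constant (`tau_K = 2` ms) twentyfold; the test
suite uses `dt = 0.2` ms on the 8 s day. Spikes are detected online as
upward 0 mV crossings with a 2 ms refractory period and
linearly-interpolated crossing times. Availability is clamped to `[0, 1]`
after each step as a safety net (inactive in normal operation); a step
producing a non-finite state or `|V| > 500` mV aborts with a diagnostic
naming the offending neuron. Noise draws come from R's RNG (one
`set.seed()` per run), drawn only for equations with nonzero intensity so
that, e.g., B-noise-only runs consume identical streams regardless of `N`.

The silent initial state is the self-consistent coupled rest point
(Gauss-Seidel iteration with scalar root finding, availability fully
recovered at `g = 1`), identical across A neurons.

## Problem sizes used by the tests

The shipped test suite runs the calibration and reference-state checks on
the full 24 s day at `dt = 0.1` ms, and the sweep-shaped checks (diversity
resonance over 8 widths x 3 threshold seeds, noise-on-B over 8 intensities
x 3 seeds, 10 periods each) on the 8 s day at `dt = 0.2` ms — the same
dynamics under the documented rescaling, chosen as a deliberate
compromise between statistical resolution and suite runtime.

## What the synthetic generator does and does not emulate

`synthetic_spike_train()` reproduces the *structure* the metric consumes —
tonic spiking confined to prescribed windows — not the biophysics: no
spike-shape, no refractory violations, no slow drift of firing rate within
an episode, and jitter is uniform rather than arising from membrane noise.
Tests passing on these fixtures validate the scoring layer, not the
simulator; the simulator-level claims are tested separately on simulated
spike trains.

## Known limitations

One glutamate interneuron and complete gap-junction coupling only; a
single orexin species; no REM/NREM ultradian structure; the circadian
drive is a rectangular pulse train rather than a realistic light-driven
waveform; noise and diversity are studied separately, not in combination.
The quantitative location of the resonance optimum depends on the
re-derived default parameter set and is asserted as a curve-shape
property, not a position.
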