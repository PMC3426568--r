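#' Circadian pulse current
#'
#' Evaluates the periodic rectangular pulse train at time `t`: the current is
#' `delta_I` inside the half-open window `[k*period, k*period + delta_T)` for
#' integer `k`, and zero elsewhere. Vectorized over `t`.
#'
#' @param t Time (ms), >= 0; vectorized.
#' @param spec A [stimulus_spec()].
#' @return Current in uA/cm^2.
#' @export
#' @examples
#' s <- stimulus_spec(delta_I = 2, delta_T = 1000, period = 24000)
#' pulse_current(c(500, 23999, 24500), s)
pulse_current <- function(t, spec) {
  stopifnot(inherits(spec, "somnox_stimulus"), all(t >= 0))
  if (!spec$enabled) return(rep(0, length(t)))
  tm <- t %% spec$period
  ifelse(tm < spec$delta_T, spec$delta_I, 0)
}
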