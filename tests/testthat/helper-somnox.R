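# Shared fixtures. Most dynamical tests run on the short rescaled day
# (T_day = 8 s, slow constants scaled by 1/3, dt = 0.2 ms) so the whole
# suite stays fast; the acceptance tests that pin printed numbers use the
# full 24 s day.

test_day <- 8000

test_params <- function(...) rescale_day(model_params(...), test_day)

test_stimulus <- function(delta_I = 2, enabled = TRUE)
  stimulus_spec(delta_I = delta_I, delta_T = 1000 / 3, period = test_day,
                enabled = enabled)

test_config <- function(N = 2, delta_I = 2, params = test_params(), ...)
  network_config(N = N, params = params,
                 stimulus = test_stimulus(delta_I = delta_I), ...)

# lazy cache for expensive shared objects (built once per test run)
.somnox_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .somnox_cache))
    assign(key, force(expr), envir = .somnox_cache)
  get(key, envir = .somnox_cache)
}

# test-scale critical pulse height and period-2 reference configuration
test_critical_height <- function() {
  cached("dIc8", find_pulse_threshold(test_config(N = 20), lo = 0.2, hi = 2,
                                      tol = 0.01, dt = 0.2))
}

test_reference_config <- function() {
  cached("ref8", make_reference_config(test_config(N = 20), dt = 0.2,
                                       critical_height = test_critical_height()))
}

# full-scale (24 s day) default network and its critical height
full_config <- function(N = 20, delta_I = 2)
  network_config(N = N, stimulus = stimulus_spec(delta_I = delta_I))

full_critical_height <- function() {
  cached("dIc24", find_pulse_threshold(full_config(), lo = 0.2, hi = 2,
                                       tol = 0.01, dt = 0.1))
}

full_calibrated_params <- function() {
  cached("cal24", {
    sup <- full_config()
    sup$stimulus$delta_I <- 1.05 * full_critical_height()
    calibrate_orexin_timescales(sup, wake_target_fraction = 2 / 3,
                                tol = 0.03, dt = 0.1)
  })
}
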