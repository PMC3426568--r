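test_that("sigmoid activation has the right shape, symmetry and limits", {
  expect_equal(sigmoid_activation(-25, 0.25, -25), 0.5)
  expect_equal(sigmoid_activation(975, 0.25, -25), 1, tolerance = 1e-12)
  # V = Vh + ln(3)/s puts the sigmoid at 3/4: 1/(1+exp(-ln 3)) = 0.75
  expect_equal(sigmoid_activation(-25 + 4 * log(3), 0.25, -25), 0.75,
               tolerance = 1e-12)
  V <- seq(-100, 60, by = 0.5)
  expect_true(all(diff(sigmoid_activation(V, 0.25, -30)) > 0))
  expect_error(sigmoid_activation(NaN, 0.25, -25), "non-finite")
})

test_that("ionic currents follow g * a * (V - V_eq) with kind-selected pairs", {
  p <- model_params()
  # zero driving force at the equilibrium potential
  expect_equal(ionic_current("L", p$V_L, params = p), 0)
  expect_equal(ionic_current("K", p$V_K, 0.5, p), 0)
  expect_equal(ionic_current("gl", p$V_gl, 0.7, p), 0)
  # linear law for the leak
  expect_equal(ionic_current("L", p$V_L + 10, params = p), p$g_L * 10)
  # Na composes its instantaneous sigmoid with the linear law
  expect_equal(ionic_current("Na", p$Vh_Na, params = p),
               0.5 * p$g_Na * (p$Vh_Na - p$V_Na))
  expect_error(ionic_current("Ca", -60, 1, p), "arg")
  expect_error(ionic_current("K", -60, 1.5, p), "0, 1")
})

test_that("permutation symmetry: identical A neurons get identical derivatives and no gap current", {
  cfg <- test_config(N = 5)
  st <- initial_silent_state(cfg)
  st$V_A <- rep(-48, 5)
  st$aK_A <- rep(0.2, 5)
  d <- derivatives(st, t = 10, cfg)
  expect_equal(length(unique(d$V_A)), 1)
  expect_equal(length(unique(d$aK_A)), 1)
  # gap currents cancel exactly: same dV as the N = 1 network
  cfg1 <- test_config(N = 1)
  st1 <- initial_silent_state(cfg1)
  st1$V_A <- -48
  st1$aK_A <- 0.2
  d1 <- derivatives(st1, t = 10, cfg1)
  expect_equal(d$V_A[1], d1$V_A)
})

test_that("with N = 1 the network RHS reduces to the two-neuron model term by term", {
  cfg <- test_config(N = 1)
  p <- cfg$params
  st <- initial_silent_state(cfg)
  st$V_A <- -40; st$V_B <- -55; st$aK_A <- 0.3; st$aK_B <- 0.1
  st$a_glBA <- 0.2; st$a_glAB <- 0.4; st$a_ox <- 0.15; st$g_ox_avail <- 0.9
  d <- derivatives(st, t = 100, cfg)
  sig <- sigmoid_activation
  I_ext <- pulse_current(100, cfg$stimulus)
  dV_A <- (-p$g_L * (st$V_A - p$V_L) -
             p$g_Na * sig(st$V_A, p$s_Na, p$Vh_Na) * (st$V_A - p$V_Na) -
             p$g_K * st$aK_A * (st$V_A - p$V_K) -
             p$g_gl * st$a_glBA * (st$V_A - p$V_gl) + I_ext) / p$C_m
  dV_B <- (-p$g_L * (st$V_B - p$V_L) -
             p$g_Na * sig(st$V_B, p$s_Na, p$Vh_Na) * (st$V_B - p$V_Na) -
             p$g_K * st$aK_B * (st$V_B - p$V_K) -
             p$g_gl * st$a_glAB * (st$V_B - p$V_gl) -
             p$g_ox * st$a_ox * (st$V_B - p$V_ox)) / p$C_m
  expect_equal(d$V_A, dV_A)
  expect_equal(d$V_B, dV_B)
  expect_equal(d$aK_A, (sig(st$V_A, p$s_K, p$Vh_K) - st$aK_A) / p$tau_K)
  expect_equal(d$a_glBA,
               (sig(st$V_B, p$s_gl, p$theta_gl_mean) - st$a_glBA) / p$tau_gl)
  expect_equal(d$a_glAB,
               (sig(st$V_A, p$s_gl, p$theta_gl_mean) - st$a_glAB) / p$tau_gl)
  expect_equal(d$a_ox,
               (sig(st$g_ox_avail, p$gate_k, p$g_crit) *
                  sig(st$V_A, p$s_ox, p$theta_ox) - st$a_ox) / p$tau_ox)
  expect_equal(d$g_ox_avail,
               (1 - st$g_ox_avail) / p$theta_rec -
                 sig(st$V_A, p$s_ox, p$theta_ox) * st$g_ox_avail / p$theta_dep)
})

test_that("the silent state is a fixed point of the no-stimulus dynamics", {
  cfg <- test_config(N = 3)
  cfg$stimulus$enabled <- FALSE
  st <- initial_silent_state(cfg)
  # availability is the one slowly drifting variable (depletion at rest is
  # tiny but nonzero); zero it out of the residual
  d <- derivatives(st, t = 0, cfg)
  resid <- c(d$V_A, d$aK_A, d$a_glBA, d$a_glAB, d$V_B, d$aK_B)
  expect_lt(max(abs(resid)), 1e-8)
  expect_lt(max(abs(d$a_ox)), 1e-5)
})

test_that("silent initial state is identical across A neurons with full availability", {
  cfg <- test_config(N = 4)
  st <- initial_silent_state(cfg)
  expect_equal(st$g_ox_avail, rep(1, 4))
  expect_equal(length(unique(st$V_A)), 1)
  # B rests slightly depolarized relative to A (resting orexin/glutamate
  # input), but both sit near the leak potential
  expect_lt(abs(st$V_A[1] - st$V_B), 1)
})

test_that("without external input the network stays silent; a strong pulse wakes it beyond the pulse", {
  cfg <- test_config(N = 2)
  cfg$stimulus$enabled <- FALSE
  sim <- run_simulation(cfg, n_periods = 1, dt = 0.2, record_traces = FALSE)
  expect_equal(nrow(sim$spikes), 0)

  cfg2 <- test_config(N = 2, delta_I = 2)
  sim2 <- run_simulation(cfg2, duration = 3000, dt = 0.2,
                         record_traces = FALSE)
  spB <- sim2$spike_times[["B"]]
  expect_gt(length(spB), 10)
  # tonic firing outlasts the pulse (reciprocal excitation)
  expect_gt(max(spB), 2 * cfg2$stimulus$delta_T)
})

test_that("trajectories stay bounded and activations stay in [0, 1]", {
  cfg <- test_config(N = 3, delta_I = 2)
  sim <- run_simulation(cfg, n_periods = 2, dt = 0.2, record_every = 1)
  p <- cfg$params
  expect_true(all(sim$traces$V_B > p$V_K - 5 & sim$traces$V_B < p$V_Na + 5))
  expect_true(all(sim$traces$V_A1 > p$V_K - 5 & sim$traces$V_A1 < p$V_Na + 5))
  expect_true(all(sim$traces$g_avail_mean >= 0 & sim$traces$g_avail_mean <= 1))
  expect_true(all(sim$traces$a_ox_mean >= 0 & sim$traces$a_ox_mean <= 1))
  fs <- sim$final_state
  acts <- c(fs$aK_A, fs$a_glBA, fs$a_ox, fs$g_ox_avail, fs$a_glAB, fs$aK_B)
  expect_true(all(acts >= 0 & acts <= 1))
})

test_that("parameter validation names every offending field", {
  expect_error(model_params(g_L = -1), "g_L")
  expect_error(model_params(g_crit = 1.2), "g_crit")
  expect_error(model_params(tau_K = 50), "tau_K < tau_gl")
  expect_error(model_params(nonsense = 1), "unknown parameter")
  expect_silent(validate_params(model_params()))
})

test_that("network state round-trips through the flat integrator layout", {
  cfg <- test_config(N = 3)
  st <- initial_silent_state(cfg)
  y <- pack_state(st)
  expect_length(y, 5 * 3 + 3 + 2)
  st2 <- unpack_state(y, N = 3)
  expect_equal(st2, st)
})
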