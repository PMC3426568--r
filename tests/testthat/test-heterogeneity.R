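test_that("threshold density is a symmetric, unimodal, normalized bell", {
  for (x in c(1, 2, 5))
    expect_equal(threshold_density(-30 + x, -30, 2),
                 threshold_density(-30 - x, -30, 2))
  q <- stats::integrate(threshold_density, -30 - 80, -30 + 80,
                        mean = -30, width = 2, rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-6)
  # mode at the mean
  expect_gt(threshold_density(-30, -30, 2), threshold_density(-29, -30, 2))
  # standard deviation (pi / sqrt(3)) * w by numerical second moment
  m2 <- stats::integrate(function(th) (th + 30)^2 * threshold_density(th, -30, 2),
                         -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(sqrt(m2), pi / sqrt(3) * 2, tolerance = 1e-4)
  expect_error(threshold_density(0, 0, 0), "width")
})

test_that("threshold sampling is reproducible, degenerate at width 0, and centred", {
  expect_equal(sample_thresholds(7, -30, 0, seed = 99), rep(-30, 7))
  a <- sample_thresholds(50, -30, 2, seed = 5)
  b <- sample_thresholds(50, -30, 2, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, sample_thresholds(50, -30, 2, seed = 6)))
  # CLT bound on the sample mean with sd = (pi/sqrt 3) * w
  big <- sample_thresholds(10000, -30, 2, seed = 1)
  expect_lt(abs(mean(big) + 30), 3 * (pi / sqrt(3)) * 2 / sqrt(10000))
  # sampling must not disturb the caller's RNG stream
  set.seed(42); r1 <- runif(1)
  set.seed(42); invisible(sample_thresholds(10, 0, 1, seed = 3)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("effective equilibrium interpolates between the bare sigmoid and the density CDF", {
  s <- 0.25; mu <- -30
  # small-diversity limit: the homogeneous sigmoid
  for (V in c(mu - 10, mu, mu + 10))
    expect_equal(effective_equilibrium(V, mu, 1e-6, s),
                 sigmoid_activation(V, s, mu), tolerance = 1e-6)
  # symmetry point for any width
  for (w in c(0.5, 2, 10, 40))
    expect_equal(effective_equilibrium(mu, mu, w, s), 0.5, tolerance = 1e-7)
  # large-diversity limit: the logistic CDF with steepness 1/w. At w = 40
  # the sigmoid's own scale (1/s = 4 mV) still adds in quadrature
  # (sqrt(40^2 + 4^2) ~ 40.2), so the residual is ~2e-3; doubling w halves
  # it below 1e-3
  V <- c(mu - 60, mu - 20, mu + 20, mu + 60)
  expect_lt(max(abs(effective_equilibrium(V, mu, 40, s) -
                      stats::plogis(V, location = mu, scale = 40))), 2e-3)
  V2 <- c(mu - 120, mu - 40, mu + 40, mu + 120)
  expect_lt(max(abs(effective_equilibrium(V2, mu, 80, s) -
                      stats::plogis(V2, location = mu, scale = 80))), 1e-3)
  # monotone in V, bounded in [0, 1]
  Vg <- seq(mu - 50, mu + 50, by = 2)
  ee <- effective_equilibrium(Vg, mu, 4, s)
  expect_true(all(diff(ee) > 0))
  expect_true(all(ee >= 0 & ee <= 1))
})

test_that("finite-N threshold mixtures converge to the integral form roughly as 1/sqrt(N)", {
  s <- 0.25; mu <- -30; w <- 4
  Vg <- seq(mu - 30, mu + 30, by = 3)
  exact <- effective_equilibrium(Vg, mu, w, s)
  sup_err <- function(N, seed) {
    th <- sample_thresholds(N, mu, w, seed = seed)
    mix <- vapply(Vg, function(v) mean(sigmoid_activation(v, s, th)),
                  numeric(1))
    max(abs(mix - exact))
  }
  e_small <- mean(vapply(1:6, function(k) sup_err(40, k), numeric(1)))
  e_big <- mean(vapply(1:6, function(k) sup_err(4000, k), numeric(1)))
  expect_lt(e_big, e_small / 3) # expected factor 10; demand at least 3
})

test_that("fitted effective steepness falls monotonically from the bare slope towards 1/w", {
  s <- 0.25
  expect_equal(fit_effective_slope(0, s), s)
  expect_equal(fit_effective_slope(0.01, s), s, tolerance = 1e-3)
  widths <- c(0, 1, 2, 4, 8, 16)
  fits <- vapply(widths, fit_effective_slope, numeric(1), slope = s)
  expect_true(all(diff(fits) < 0))
  expect_lt(fits[widths == 16], s / 2)
  # approaches the CDF limit 1/w from its convolution-broadened side
  expect_equal(fits[widths == 16], 1 / sqrt(16^2 + (1 / s)^2),
               tolerance = 0.02)
})

test_that("A-to-B diversity reduces exactly to a two-neuron model with a threshold mixture", {
  base <- test_config(N = 6, delta_I = 2,
                      diversity = diversity_spec("AB", width = 3, seed = 11))
  red <- effective_two_neuron_config(base)
  expect_equal(red$N, 1L)
  expect_equal(red$thresholds_AB, base$thresholds_AB)
  simf <- run_simulation(base, duration = 4000, dt = 0.2, record_every = 1)
  simr <- run_simulation(red, duration = 4000, dt = 0.2, record_every = 1)
  expect_lt(max(abs(simf$traces$V_B - simr$traces$V_B)), 1e-6)
  # width-0 reduction equals the plain two-neuron model
  hom <- test_config(N = 5, delta_I = 2)
  red0 <- effective_two_neuron_config(hom)
  sim0 <- run_simulation(red0, duration = 3000, dt = 0.2, record_every = 1)
  sim1 <- run_simulation(test_config(N = 1, delta_I = 2), duration = 3000,
                         dt = 0.2, record_every = 1)
  expect_lt(max(abs(sim0$traces$V_B - sim1$traces$V_B)), 1e-9)
  # preconditions enforced
  noisy <- test_config(N = 3, noise = noise_spec(D_A = 1))
  expect_error(effective_two_neuron_config(noisy), "noise")
  divBA <- test_config(N = 3, diversity = diversity_spec("BA", width = 2))
  expect_error(effective_two_neuron_config(divBA), "homogeneous|A-to-B")
})
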