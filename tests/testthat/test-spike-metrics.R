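test_that("spike detection counts threshold crossings with refractory suppression", {
  # constant sub-threshold trace
  expect_length(detect_spikes(rep(-60, 1000), dt = 1), 0)
  # 10 Hz sinusoid about -40 mV with 40 mV amplitude crosses 0 upward 10x/s
  t <- seq(0, 1000, by = 0.5)
  V <- -40 + 40 * sin(2 * pi * 10 * t / 1000)
  expect_length(detect_spikes(V, dt = 0.5, spike_threshold = 0), 10)
  # double peak within the refractory period counts once
  V2 <- rep(-60, 100)
  V2[c(10, 12)] <- 10 # two upward crossings 1 ms apart at dt = 0.5
  expect_length(detect_spikes(V2, dt = 0.5, refractory = 2), 1)
  # linear interpolation places the crossing between samples
  V3 <- c(-10, 10)
  expect_equal(detect_spikes(V3, dt = 1), 0.5)
})

test_that("wake intervals follow the capped-extension union rule", {
  iv <- wake_intervals(c(0, 100, 200), gap = 250)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 0)
  expect_equal(iv$end, 450)
  expect_equal(sum(iv$end - iv$start), 450)
  expect_equal(nrow(wake_intervals(numeric(0))), 0)
  iv2 <- wake_intervals(10000, gap = 250)
  expect_equal(unlist(iv2, use.names = FALSE), c(10000, 10250))
  # far-apart spikes give disjoint intervals
  iv3 <- wake_intervals(c(0, 1000), gap = 250)
  expect_equal(nrow(iv3), 2)
  expect_error(wake_intervals(c(5, 1)), "sorted")
})

test_that("Q hits its canonical values +1, 0, -1 on ideal fixtures", {
  T <- 24000; f_w <- 2 / 3; M <- 6
  day_windows <- data.frame(start = (0:(M - 1)) * T,
                            end = (0:(M - 1)) * T + f_w * T)
  tonic_day <- synthetic_spike_train(day_windows, isi = 20)
  q1 <- quality_coefficient(tonic_day, T = T, f_w = f_w, n_periods = M)
  expect_equal(q1$Q, 1, tolerance = 0.02)

  q0 <- quality_coefficient(numeric(0), T = T, f_w = f_w, n_periods = M)
  expect_equal(q0$Q, 0)

  night_windows <- data.frame(start = (0:(M - 1)) * T + f_w * T,
                              end = (1:M) * T)
  tonic_night <- synthetic_spike_train(night_windows, isi = 20)
  qm1 <- quality_coefficient(tonic_night, T = T, f_w = f_w, n_periods = M)
  expect_equal(qm1$Q, -1, tolerance = 0.02)
  expect_true(all(qm1$periods$W_day_ms >= 0))
})

test_that("Q from the interval rule agrees with a 1-ms-grid occupancy oracle", {
  T <- 24000; f_w <- 2 / 3; M <- 4; gap <- 250
  grid_Q <- function(st, skip) {
    tt <- seq(skip * T, M * T - 1, by = 1) # 1 ms grid, left endpoints
    # awake iff within gap of the most recent spike (equivalent to the
    # capped-extension interval union)
    awake <- vapply(tt, function(x) {
      prev <- st[st <= x]
      length(prev) > 0 && (x - max(prev)) < gap
    }, logical(1))
    phase <- tt %% T
    day <- phase < f_w * T
    Wd <- tapply(awake & day, floor(tt / T), sum)
    Wn <- tapply(awake & !day, floor(tt / T), sum)
    mean(Wd) / (f_w * T) - mean(Wn) / ((1 - f_w) * T)
  }
  set.seed(33)
  for (k in 1:50) {
    n_sp <- sample(0:40, 1)
    st <- sort(runif(n_sp, 0, M * T))
    q <- quality_coefficient(st, T = T, f_w = f_w, n_periods = M,
                             gap = gap, skip_periods = 1)
    expect_equal(q$Q, grid_Q(st, skip = 1), tolerance = 0.01)
  }
})

test_that("Q is invariant under whole-period translation and monotone under spike edits", {
  T <- 8000; f_w <- 2 / 3
  windows <- data.frame(start = c(0, 2 * T), end = c(0 + f_w * T, 2 * T + 4000))
  st <- synthetic_spike_train(windows, isi = 25)
  q <- quality_coefficient(st, T = T, f_w = f_w, n_periods = 6,
                           skip_periods = 0)$Q
  q_shift <- quality_coefficient(st + 2 * T, T = T, f_w = f_w, n_periods = 8,
                                 skip_periods = 2)$Q
  expect_equal(q_shift, q, tolerance = 1e-10)
  # a night spike never increases Q; extending day coverage never decreases it
  with_night <- sort(c(st, 1 * T + f_w * T + 2000))
  q_night <- quality_coefficient(with_night, T = T, f_w = f_w, n_periods = 6,
                                 skip_periods = 0)$Q
  expect_lte(q_night, q)
  with_day <- sort(c(st, 3 * T + 1000))
  q_day <- quality_coefficient(with_day, T = T, f_w = f_w, n_periods = 6,
                               skip_periods = 0)$Q
  expect_gte(q_day, q)
})

test_that("an isolated nightly spike reduces Q by about gap / ((1 - f_w) T) per period", {
  T <- 24000; f_w <- 2 / 3; M <- 5; gap <- 250
  day_windows <- data.frame(start = (0:(M - 1)) * T,
                            end = (0:(M - 1)) * T + f_w * T)
  st <- synthetic_spike_train(day_windows, isi = 20)
  q_base <- quality_coefficient(st, T = T, f_w = f_w, n_periods = M,
                                gap = gap)$Q
  night_spikes <- (1:(M - 1)) * T + f_w * T + 4000
  q_pert <- quality_coefficient(sort(c(st, night_spikes)), T = T, f_w = f_w,
                                n_periods = M, gap = gap)$Q
  expect_equal(q_base - q_pert, gap / ((1 - f_w) * T), tolerance = 1e-6)
})

test_that("periodicity classification distinguishes regular, alternating and irregular wake", {
  T <- 24000; f_w <- 2 / 3
  expect_equal(classify_periodicity(c(14, 14.1, 13.9, 14, 14, 14) * 1000,
                                    f_w, T), "period1")
  expect_equal(classify_periodicity(c(14, 0.3, 14.2, 0.2, 13.8, 0.4) * 1000,
                                    f_w, T), "period2")
  expect_equal(classify_periodicity(c(14, 0.3, 0.2, 14, 14, 0.1) * 1000,
                                    f_w, T), "irregular")
  expect_equal(classify_periodicity(rep(0, 6), f_w, T), "irregular")
  expect_error(classify_periodicity(c(14, 0, 14) * 1000, f_w, T),
               "at least 6")
})

test_that("the synthetic train generator respects windows, jitter bounds and seeds", {
  w <- data.frame(start = c(0, 5000), end = c(1000, 6000))
  st <- synthetic_spike_train(w, isi = 100, jitter = 20, seed = 4)
  expect_true(all((st >= 0 & st < 1000) | (st >= 5000 & st < 6000)))
  expect_identical(st, synthetic_spike_train(w, isi = 100, jitter = 20,
                                             seed = 4))
  expect_length(synthetic_spike_train(w[0, ], isi = 100), 0)
  over <- data.frame(start = c(0, 500), end = c(1000, 1500))
  expect_error(synthetic_spike_train(over, isi = 100), "overlap")
})

test_that("tidy and glance summarise reports and simulations", {
  T <- 8000
  st <- synthetic_spike_train(data.frame(start = 0, end = 3 * T), isi = 25)
  q <- quality_coefficient(st, T = T, n_periods = 3)
  td <- tidy(q)
  expect_true(all(c("period", "day_fraction", "night_fraction") %in%
                    names(td)))
  gl <- glance(q)
  expect_equal(gl$Q, q$Q)
  expect_equal(gl$n_periods, 2)
})
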