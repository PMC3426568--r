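#' Detect spikes in a sampled voltage trace
#'
#' Upward crossings of `spike_threshold`, with crossings closer than
#' `refractory` to the previous accepted spike suppressed, and crossing
#' times refined by linear interpolation between samples.
#'
#' @param V_trace Sampled membrane potential (mV).
#' @param dt Sampling interval (ms).
#' @param spike_threshold Threshold (mV), default 0.
#' @param refractory Minimum separation between spikes (ms), default 2; must
#'   exceed `dt`.
#' @param t0 Time of the first sample (ms).
#' @return Numeric vector of spike times (ms), strictly increasing.
#' @export
detect_spikes <- function(V_trace, dt, spike_threshold = 0, refractory = 2,
                          t0 = 0) {
  stopifnot(refractory > dt, dt > 0)
  n <- length(V_trace)
  if (n < 2) return(numeric(0))
  below <- V_trace[-n] < spike_threshold
  above <- V_trace[-1] >= spike_threshold
  idx <- which(below & above)
  if (!length(idx)) return(numeric(0))
  frac <- (spike_threshold - V_trace[idx]) / (V_trace[idx + 1] - V_trace[idx])
  times <- t0 + (idx - 1 + frac) * dt
  keep <- logical(length(times))
  last <- -Inf
  for (k in seq_along(times)) {
    if (times[k] - last > refractory) {
      keep[k] <- TRUE
      last <- times[k]
    }
  }
  times[keep]
}

#' Wake intervals from a spike train
#'
#' The wake (spiking) state is represented as a union of intervals: each
#' spike at time `t_k` contributes `[t_k, min(t_{k+1}, t_k + gap))`, i.e.
#' wakefulness extends from each spike until the next spike or for at most
#' `gap` ms. Under tonic firing (inter-spike intervals well below `gap`) this
#' yields one contiguous wake episode; an isolated spike contributes a short
#' awakening of length `gap`.
#'
#' @param spike_times Sorted spike times (ms).
#' @param gap Maximal per-spike wake extension (ms), default 150.
#' @return A tibble with columns `start`, `end` (ms), disjoint and sorted.
#' @export
#' @examples
#' wake_intervals(c(0, 100, 200), gap = 250) # one interval [0, 450]
wake_intervals <- function(spike_times, gap = 150) {
  stopifnot(gap > 0)
  if (!length(spike_times))
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  if (is.unsorted(spike_times, strictly = FALSE))
    stop("spike times must be sorted")
  n <- length(spike_times)
  ends <- pmin(c(spike_times[-1], Inf), spike_times + gap)
  # merge touching/overlapping intervals
  new_block <- c(TRUE, spike_times[-1] > ends[-n])
  block <- cumsum(new_block)
  tibble::tibble(
    start = as.numeric(tapply(spike_times, block, min)),
    end = as.numeric(tapply(ends, block, max))
  )
}

# total overlap (ms) of wake intervals with window [lo, hi)
interval_overlap <- function(iv, lo, hi) {
  if (!nrow(iv)) return(0)
  sum(pmax(0, pmin(iv$end, hi) - pmax(iv$start, lo)))
}

#' Sleep-wake quality coefficient Q
#'
#' Splits each daily period of length `T` into a day window (the first
#' fraction `f_w`) and the complementary night window, accumulates the wake
#' time (from the interval rule of [wake_intervals()]) falling in each, and
#' scores the cycle as
#' \deqn{Q = \langle W_d\rangle / (f_w T) - \langle W_n\rangle / ((1-f_w) T),}
#' the mean day-wake fraction minus the mean night-wake fraction. `Q = 1` is
#' the optimal cycle (awake all day, asleep all night), `Q = -1` the fully
#' inverted one, and `Q = 0` e.g. total silence. The first `skip_periods`
#' periods are discarded as transient.
#'
#' @param spike_times Sorted spike times of the scored neuron (ms).
#' @param T Daily period (ms).
#' @param f_w Wake fraction of the day, in (0, 1); default 2/3 (16 h of 24).
#' @param n_periods Number of simulated periods covered by the train.
#' @param gap Wake-interval extension parameter (ms), default 150.
#' @param skip_periods Initial periods to discard, default 1.
#' @return An object of class `somnox_qreport`: list with `Q`, `f_w`,
#'   `T`, `n_periods`, `skip_periods`, `gap`, and `periods`, a tibble with
#'   one row per retained period (`period`, `W_day_ms`, `W_night_ms`).
#' @export
quality_coefficient <- function(spike_times, T, f_w = 2 / 3, n_periods,
                                gap = 150, skip_periods = 1) {
  if (T <= 0) stop("T must be > 0")
  stopifnot(f_w > 0, f_w < 1, n_periods >= skip_periods + 1)
  iv <- wake_intervals(spike_times, gap = gap)
  periods <- seq.int(skip_periods, n_periods - 1)
  W_d <- vapply(periods, function(n)
    interval_overlap(iv, n * T, n * T + f_w * T), numeric(1))
  W_n <- vapply(periods, function(n)
    interval_overlap(iv, n * T + f_w * T, (n + 1) * T), numeric(1))
  Q <- mean(W_d) / (f_w * T) - mean(W_n) / ((1 - f_w) * T)
  structure(list(
    Q = Q, f_w = f_w, T = T, n_periods = n_periods,
    skip_periods = skip_periods, gap = gap,
    periods = tibble::tibble(period = periods, W_day_ms = W_d,
                             W_night_ms = W_n)
  ), class = "somnox_qreport")
}

#' @export
print.somnox_qreport <- function(x, ...) {
  cat(sprintf("<somnox Q report>  Q = %.4f over %d periods (f_w = %.3f, T = %g ms)\n",
              x$Q, nrow(x$periods), x$f_w, x$T))
  invisible(x)
}

#' Classify the periodicity of the wake response
#'
#' A period counts as a "wake day" when its day-wake time reaches at least a
#' quarter of the day window. The response is `"period1"` when every period
#' is a wake day, `"period2"` when wake days strictly alternate with sleep
#' days, and `"irregular"` otherwise.
#'
#' @param W_day Per-period day-wake times (ms), at least 6 periods.
#' @param f_w Wake fraction, default 2/3.
#' @param T Daily period (ms).
#' @return One of `"period1"`, `"period2"`, `"irregular"`.
#' @export
classify_periodicity <- function(W_day, f_w = 2 / 3, T) {
  if (length(W_day) < 6) stop("need at least 6 periods to classify")
  wake_day <- W_day >= 0.25 * f_w * T
  if (all(wake_day)) return("period1")
  n <- length(wake_day)
  if (any(wake_day) && all(wake_day[-1] != wake_day[-n])) return("period2")
  "irregular"
}

#' Synthetic day/night-structured spike train
#'
#' Fixture generator: emits tonically spaced spikes (inter-spike interval
#' `isi`, optionally jittered) inside each requested wake window, so the
#' metric layer can be exercised independently of the simulator.
#'
#' @param windows A data frame with columns `start`, `end` (ms): the wake
#'   windows. Must be non-overlapping.
#' @param isi Inter-spike interval (ms), > 0.
#' @param jitter Half-width of uniform jitter on each spike time (ms).
#' @param seed RNG seed for the jitter.
#' @return Sorted numeric vector of spike times (ms).
#' @export
#' @examples
#' st <- synthetic_spike_train(data.frame(start = 0, end = 16000), isi = 20)
synthetic_spike_train <- function(windows, isi, jitter = 0, seed = 1L) {
  stopifnot(isi > 0, jitter >= 0)
  if (!nrow(windows)) return(numeric(0))
  w <- windows[order(windows$start), , drop = FALSE]
  if (any(w$end <= w$start)) stop("windows must have end > start")
  if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)]))
    stop("wake windows must not overlap")
  spikes <- withr::with_seed(as.integer(seed), {
    unlist(lapply(seq_len(nrow(w)), function(i) {
      s <- seq(w$start[i], w$end[i], by = isi)
      if (jitter > 0)
        s <- s + stats::runif(length(s), -jitter, jitter)
      s[s >= w$start[i] & s < w$end[i]]
    }))
  })
  sort(spikes)
}
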