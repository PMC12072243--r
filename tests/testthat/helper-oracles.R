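# Brute-force oracles (explicit sample-by-sample loops) and constructed
# trace fixtures shared across the suite.

# exhaustive threshold-crossing scan mirroring the RDP duration definition:
# baseline = mean filtered V over the 500 ms before onset, duration = first
# upward crossing of baseline+thr after offset to the next downward crossing
oracle_rdp_ms <- function(v_filt, fs, t_on, t_off, thr_mV = 10) {
  i_on <- as.integer(floor(t_on * fs + 1e-9)) + 1L
  i_off <- as.integer(floor(t_off * fs + 1e-9)) + 1L
  b0 <- max(1L, as.integer(floor((t_on - 0.5) * fs + 1e-9)) + 1L)
  base <- mean(v_filt[b0:(i_on - 1L)])
  thr <- base + thr_mV
  n <- length(v_filt)
  u <- NA_integer_
  for (i in i_off:n) {
    if (v_filt[i] > thr && (i == i_off || v_filt[i - 1L] <= thr)) {
      u <- i
      break
    }
  }
  if (is.na(u)) return(list(rdp_ms = 0, censored = FALSE))
  d <- NA_integer_
  for (i in u:n) {
    if (v_filt[i] <= thr) { d <- i; break }
  }
  if (is.na(d)) {
    return(list(rdp_ms = (n - u) / fs * 1000, censored = TRUE))
  }
  list(rdp_ms = (d - u) / fs * 1000, censored = FALSE)
}

# local-maxima spike scan: one event per contiguous suprathreshold run
# (position of the run maximum), runs closer than the refractory floor
# merged keeping the taller peak
oracle_spike_idx <- function(v, fs, thr_mV = -20, refractory_ms = 2) {
  n <- length(v)
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    if (v[i] > thr_mV) {
      j <- i
      while (j < n && v[j + 1L] > thr_mV) j <- j + 1L
      seg <- i:j
      peaks <- c(peaks, seg[which.max(v[seg])])
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(peaks) < 2) return(peaks)
  min_gap <- refractory_ms / 1000 * fs
  keep <- rep(TRUE, length(peaks))
  last <- 1L
  for (k in 2:length(peaks)) {
    if (peaks[k] - peaks[last] < min_gap) {
      if (v[peaks[k]] > v[peaks[last]]) { keep[last] <- FALSE; last <- k }
      else keep[k] <- FALSE
    } else last <- k
  }
  peaks[keep]
}

# count of distinct excursions above a threshold inside a window
oracle_excursions <- function(v, thr) {
  cnt <- 0L
  above <- FALSE
  for (i in seq_along(v)) {
    if (v[i] > thr && !above) { cnt <- cnt + 1L; above <- TRUE }
    if (v[i] <= thr) above <- FALSE
  }
  cnt
}

# trapezoidal hump a fixed height above a baseline, spike-free
make_trapezoid_trace <- function(fs = 1000, baseline = -60, height = 15,
                                 t_on = 1, t_off = 2, hump_from = 2.1,
                                 hump_to = 2.6, t_total = 8, ramp = 0.02,
                                 step_mV = -20) {
  tt <- seq(0, t_total - 1 / fs, by = 1 / fs)
  v <- rep(baseline, length(tt))
  v[tt >= t_on & tt < t_off] <- baseline + step_mV
  up <- tt >= hump_from & tt < hump_to
  v[up] <- baseline + height
  ramp_in <- tt >= (hump_from - ramp) & tt < hump_from
  v[ramp_in] <- baseline + height * (tt[ramp_in] - (hump_from - ramp)) / ramp
  ramp_out <- tt >= hump_to & tt < (hump_to + ramp)
  v[ramp_out] <- baseline + height * (1 - (tt[ramp_out] - hump_to) / ramp)
  voltageTrace(v, fs = fs)
}

# stereotyped triangular spikes at given times on a flat baseline
make_spike_train_trace <- function(spike_times, fs = 10000, t_total = 3,
                                   baseline = -60, peak = 10,
                                   half_width_ms = 1) {
  n <- round(t_total * fs)
  v <- rep(baseline, n)
  hw <- max(1L, round(half_width_ms / 1000 * fs))
  for (ts in spike_times) {
    c0 <- round(ts * fs) + 1L
    for (k in -hw:hw) {
      idx <- c0 + k
      if (idx >= 1 && idx <= n)
        v[idx] <- max(v[idx], peak - (peak - baseline) * abs(k) / hw)
    }
  }
  voltageTrace(v, fs = fs)
}

# compact protocols used by the simulator tests
short_test_protocol <- function(amp = -100, t_total = 8)
  stepProtocol(amp_pA = amp, t_total = t_total)

rdp_of <- function(params, drug = "control", amp = -100, t_total = 12) {
  pr <- stepProtocol(amp_pA = amp, t_total = t_total)
  measureRdpDuration(simulateCell(params, pr, drug = drug), pr)
}
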