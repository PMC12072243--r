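#' @include filter.R
NULL

## Per-cell feature extraction from current-clamp traces. All features are
## deterministic functions of (trace, protocol).

.idx <- function(t_s, fs) as.integer(floor(t_s * fs + 1e-9)) + 1L

.baselineWindow <- function(trace, protocol, width_s = 0.5) {
  fs <- trace@fs
  i0 <- max(1L, .idx(protocol@t_on - width_s, fs))
  i1 <- .idx(protocol@t_on, fs) - 1L
  if (i1 < i0) stop("trace/protocol mismatch: no pre-onset baseline window")
  c(i0, i1)
}

#' Detect action potentials by threshold crossing
#'
#' One event per suprathreshold excursion: an upward crossing of
#' `threshold_mV` opens an excursion, the event time is the sample of the
#' excursion's voltage peak, and events closer than `refractory_ms` are
#' merged (the larger peak wins). Peak amplitudes are measured from the
#' -60 mV holding level.
#'
#' @param trace A [VoltageTrace-class].
#' @param threshold_mV Detection threshold (default -20 mV).
#' @param refractory_ms Minimum separation of events (default 2 ms).
#' @param ref_mV Reference level for amplitudes (default -60 mV).
#' @return data.frame (`time_s`, `peak_mV`, `amp_mV`), one row per spike,
#'   strictly increasing in time.
#' @examples
#' tr <- voltageTrace(rep(-60, 4000), fs = 1000)
#' nrow(detectSpikes(tr))
#' @export
detectSpikes <- function(trace, threshold_mV = -20, refractory_ms = 2,
                         ref_mV = -60) {
  stopifnot(is(trace, "VoltageTrace"))
  v <- trace@v_mV
  fs <- trace@fs
  above <- v > threshold_mV
  d <- diff(above)
  starts <- which(d == 1L) + 1L
  ends <- which(d == -1L)
  if (above[1]) starts <- c(1L, starts)
  if (above[length(v)]) ends <- c(ends, length(v))
  if (length(starts) == 0)
    return(data.frame(time_s = numeric(), peak_mV = numeric(),
                      amp_mV = numeric()))
  peaks <- vapply(seq_along(starts), function(k) {
    seg <- starts[k]:ends[k]
    seg[which.max(v[seg])]
  }, integer(1))
  # refractory merge: drop the smaller of two peaks closer than the floor
  min_gap <- refractory_ms / 1000 * fs
  keep <- rep(TRUE, length(peaks))
  last <- 1L
  for (k in seq_along(peaks)[-1]) {
    if (peaks[k] - peaks[last] < min_gap) {
      if (v[peaks[k]] > v[peaks[last]]) { keep[last] <- FALSE; last <- k }
      else keep[k] <- FALSE
    } else last <- k
  }
  peaks <- peaks[keep]
  data.frame(time_s = (peaks - 1) / fs, peak_mV = v[peaks],
             amp_mV = v[peaks] - ref_mV)
}

#' Measure the rebound depolarizing potential duration
#'
#' The trace is low-pass filtered ([lowpass10Hz]) to remove spikes, the
#' baseline is the mean filtered voltage over the 500 ms before step onset,
#' and the RDP duration runs from the first upward crossing of
#' baseline + `threshold_mV` after step offset to the next downward
#' crossing. A trace that never crosses gives 0 ms; a trace that never
#' returns below threshold is censored at the trace end.
#'
#' @param trace A [VoltageTrace-class] from a hyperpolarizing step.
#' @param protocol The matching [StepProtocol-class].
#' @param threshold_mV Crossing threshold above baseline (default +10 mV).
#' @param min_post_s Required observation window after `t_off` (default 5 s).
#' @param filtered Set `FALSE` if the trace is already spike-free/filtered.
#' @return list(`rdp_ms`, `censored`, `peak_mV`): duration (ms), censoring
#'   flag, and the peak filtered depolarization above baseline after offset.
#' @export
measureRdpDuration <- function(trace, protocol, threshold_mV = 10,
                               min_post_s = 5, filtered = TRUE) {
  stopifnot(is(trace, "VoltageTrace"), is(protocol, "StepProtocol"))
  if (protocol@amp_pA >= 0)
    stop("RDP measurement requires a hyperpolarizing step protocol")
  fs <- trace@fs
  dur_s <- length(trace@v_mV) / fs
  if (dur_s - protocol@t_off < min_post_s - 1e-9)
    stop(sprintf("trace extends only %.2f s beyond the step offset (need >= %g s)",
                 dur_s - protocol@t_off, min_post_s))
  v <- if (filtered) lowpass10Hz(trace)@v_mV else trace@v_mV
  bw <- .baselineWindow(trace, protocol)
  baseline <- mean(v[bw[1]:bw[2]])
  thr <- baseline + threshold_mV
  i_off <- .idx(protocol@t_off, fs)
  post <- v[i_off:length(v)]
  above <- post > thr
  up <- which(diff(above) == 1L) + 1L
  if (above[1]) up <- c(1L, up)
  peak <- max(post) - baseline
  if (length(up) == 0)
    return(list(rdp_ms = 0, censored = FALSE, peak_mV = peak))
  u <- up[1]
  down <- which(!above[u:length(above)])
  if (length(down) == 0) {
    dur <- (length(above) - u) / fs * 1000
    return(list(rdp_ms = dur, censored = TRUE, peak_mV = peak))
  }
  dur <- (down[1] - 1) / fs * 1000
  list(rdp_ms = dur, censored = FALSE, peak_mV = peak)
}

#' Frequency adaptation index
#'
#' `fai = (f_init - f_final) / f_init`, where the initial firing frequency
#' is the inverse of the interval between the first two spikes of the step
#' and the final firing frequency is the spike count in the 200 ms
#' immediately before the step offset divided by 0.2 s. Evaluated on the
#' +100 pA step in the study design. A perfectly regular train spanning
#' the step gives 0; a train silent in the final 200 ms gives 1.
#'
#' @param spikes Spike table from [detectSpikes()].
#' @param protocol The [StepProtocol-class] of the depolarizing step.
#' @return list(`fai`, `f_init_Hz`, `f_final_Hz`, `defined`). With fewer
#'   than two spikes during the step the feature is undefined:
#'   `defined = FALSE` and `fai = NA` (an explicit flag, not a silent NaN).
#' @examples
#' sp <- data.frame(time_s = c(1.01, 1.03, 1.07, 1.15, 1.31, 1.63, 1.95),
#'                  peak_mV = 0, amp_mV = 60)
#' frequencyAdaptationIndex(sp, stepProtocol(amp_pA = 100))$fai
#' @export
frequencyAdaptationIndex <- function(spikes, protocol) {
  stopifnot(is(protocol, "StepProtocol"))
  tt <- spikes$time_s
  tt <- tt[tt >= protocol@t_on & tt < protocol@t_off]
  if (length(tt) < 2)
    return(list(fai = NA_real_, f_init_Hz = NA_real_, f_final_Hz = NA_real_,
                defined = FALSE))
  f_init <- 1 / (tt[2] - tt[1])
  n_final <- sum(tt >= protocol@t_off - 0.2 & tt < protocol@t_off)
  f_final <- n_final / 0.2
  list(fai = (f_init - f_final) / f_init, f_init_Hz = f_init,
       f_final_Hz = f_final, defined = TRUE)
}

#' Amplitude adaptation index
#'
#' Second spike amplitude divided by first spike amplitude during the
#' +100 pA step, amplitudes measured from -60 mV.
#'
#' @inheritParams frequencyAdaptationIndex
#' @return list(`aai`, `defined`); undefined with fewer than two spikes.
#' @export
amplitudeAdaptationIndex <- function(spikes, protocol) {
  stopifnot(is(protocol, "StepProtocol"))
  sel <- spikes$time_s >= protocol@t_on & spikes$time_s < protocol@t_off
  sp <- spikes[sel, , drop = FALSE]
  if (nrow(sp) < 2) return(list(aai = NA_real_, defined = FALSE))
  list(aai = sp$amp_mV[2] / sp$amp_mV[1], defined = TRUE)
}

#' Maximum number of spikes over the depolarizing step series
#'
#' The maximum spike count evoked by 1 s depolarizing steps from 20 to
#' 100 pA in 20 pA increments, counting only spikes inside the step window.
#'
#' @param traces Named or unnamed list of [VoltageTrace-class], one per step.
#' @param protocols Matching list of [StepProtocol-class] objects; the set
#'   of amplitudes must be exactly 20, 40, 60, 80, 100 pA.
#' @param ... Passed to [detectSpikes()].
#' @return Integer: the maximum count across steps.
#' @export
maxSpikes <- function(traces, protocols, ...) {
  amps <- vapply(protocols, function(p) p@amp_pA, numeric(1))
  need <- seq(20, 100, by = 20)
  missing_amp <- setdiff(need, amps)
  if (length(missing_amp))
    stop("missing step amplitude(s): ", paste(missing_amp, collapse = ", "), " pA")
  counts <- mapply(function(tr, p) {
    sp <- detectSpikes(tr, ...)
    sum(sp$time_s >= p@t_on & sp$time_s < p@t_off)
  }, traces, protocols)
  as.integer(max(counts))
}

#' Depolarizing sag ratio
#'
#' `(V_peak - V_steady) / V_peak`, where `V_peak` is the largest
#' hyperpolarizing deflection from baseline during the step and `V_steady`
#' the mean deflection over the last 100 ms of the step. Returns 0 when the
#' peak does not exceed the steady state.
#'
#' @param trace A [VoltageTrace-class] from a hyperpolarizing step.
#' @param protocol The matching [StepProtocol-class].
#' @return Numeric sag ratio in `[0, 1)`.
#' @export
sagRatio <- function(trace, protocol) {
  stopifnot(is(trace, "VoltageTrace"), is(protocol, "StepProtocol"))
  if (protocol@amp_pA >= 0)
    stop("sag ratio requires a hyperpolarizing step")
  fs <- trace@fs
  v <- trace@v_mV
  bw <- .baselineWindow(trace, protocol)
  baseline <- mean(v[bw[1]:bw[2]])
  i_on <- .idx(protocol@t_on, fs)
  i_off <- .idx(protocol@t_off, fs) - 1L
  defl <- baseline - v[i_on:i_off]            # positive = hyperpolarizing
  v_peak <- max(defl)
  i_st <- .idx(protocol@t_off - 0.1, fs)
  v_steady <- mean(baseline - v[i_st:i_off])
  if (v_peak <= v_steady || v_peak <= 0) return(0)
  (v_peak - v_steady) / v_peak
}

#' Resting membrane potential and input resistance
#'
#' `rmp_mV` is the mean pre-stimulus voltage; `r_in_MOhm` the steady-state
#' voltage deflection (mean over the last 100 ms of the step) divided by
#' the step current. Spikes inside either measurement window are an error.
#'
#' @param trace A [VoltageTrace-class] from a small subthreshold step.
#' @param protocol The matching [StepProtocol-class].
#' @return list(`rmp_mV`, `r_in_MOhm`, `defined`); `r_in` is undefined for
#'   a zero-amplitude step.
#' @export
passiveProperties <- function(trace, protocol) {
  stopifnot(is(trace, "VoltageTrace"), is(protocol, "StepProtocol"))
  fs <- trace@fs
  v <- trace@v_mV
  bw <- .baselineWindow(trace, protocol)
  i_off <- .idx(protocol@t_off, fs) - 1L
  i_st <- .idx(protocol@t_off - 0.1, fs)
  sp <- detectSpikes(trace)
  win_lo <- (bw[1] - 1) / fs; win_hi <- i_off / fs
  if (any(sp$time_s >= win_lo & sp$time_s <= win_hi))
    stop("spikes detected during the passive-property measurement window")
  rmp <- mean(v[bw[1]:bw[2]])
  if (protocol@amp_pA == 0)
    return(list(rmp_mV = rmp, r_in_MOhm = NA_real_, defined = FALSE))
  defl <- mean(v[i_st:i_off]) - rmp
  r_in <- defl / protocol@amp_pA * 1000      # mV/pA -> MOhm
  list(rmp_mV = rmp, r_in_MOhm = r_in, defined = TRUE)
}

# distinct excursions of a filtered trace above a threshold: count and
# per-excursion durations (ms)
.excursions <- function(v, fs, thr) {
  above <- v > thr
  d <- diff(above)
  starts <- which(d == 1L) + 1L
  ends <- which(d == -1L)
  if (above[1]) starts <- c(1L, starts)
  if (above[length(v)]) ends <- c(ends, length(v))
  n <- min(length(starts), length(ends))
  if (length(starts) == 0) return(list(n = 0L, dur_ms = numeric()))
  if (length(ends) < length(starts)) ends <- c(ends, length(v))
  list(n = length(starts), dur_ms = (ends - starts) / fs * 1000)
}

#' Classify spontaneous activity at rest
#'
#' Cells firing below `rate_threshold` (default 0.2 Hz) are silent. Firing
#' cells are classified as burst if any group of >= 3 spikes with
#' inter-spike intervals < 100 ms rides on a filtered depolarization at
#' least 5 mV above the filtered-trace median (cells showing both tonic and
#' burst patterns count as burst); otherwise tonic. The spontaneous rate is
#' the total spike count divided by the recording time, and the mean
#' spontaneous depolarization duration is measured from filtered-trace
#' crossings of median + 10 mV, as in [measureRdpDuration()].
#'
#' @param trace A [VoltageTrace-class] of >= `window_s` seconds at rest.
#' @param window_s Minimum recording length (default 20 s).
#' @param rate_threshold Silent-class boundary (Hz).
#' @return list(`spont_class` in `silent|tonic|burst`, `spont_rate_Hz`,
#'   `spont_depol_ms`).
#' @export
classifySpontaneous <- function(trace, window_s = 20, rate_threshold = 0.2) {
  stopifnot(is(trace, "VoltageTrace"))
  fs <- trace@fs
  dur <- length(trace@v_mV) / fs
  if (dur < window_s - 1e-9)
    stop(sprintf("need >= %g s of unstimulated recording (got %.1f s)",
                 window_s, dur))
  sp <- detectSpikes(trace)
  rate <- nrow(sp) / dur
  filt <- lowpass10Hz(trace)@v_mV
  base <- stats::median(filt)
  exc <- .excursions(filt, fs, base + 10)
  depol_ms <- if (exc$n > 0) mean(exc$dur_ms) else 0
  if (rate < rate_threshold)
    return(list(spont_class = "silent", spont_rate_Hz = rate,
                spont_depol_ms = depol_ms))
  is_burst <- FALSE
  if (nrow(sp) >= 3) {
    isi <- diff(sp$time_s)
    run <- 1L
    for (k in seq_along(isi)) {
      run <- if (isi[k] < 0.1) run + 1L else 1L
      if (run >= 3L) {
        idx <- (k - 1L):(k + 1L)
        ride <- mean(filt[pmin(length(filt),
                               .idx(sp$time_s[idx], fs))]) >= base + 5
        if (ride) { is_burst <- TRUE; break }
      }
    }
  }
  list(spont_class = if (is_burst) "burst" else "tonic",
       spont_rate_Hz = rate, spont_depol_ms = depol_ms)
}

#' Count post-offset rebound oscillations
#'
#' Number of distinct filtered-trace excursions above baseline + 10 mV
#' within `window_s` (default 20 s) after the offset of the
#' hyperpolarizing step; short-RDP cells often show such repetitive short
#' depolarizations in an oscillatory pattern.
#'
#' @inheritParams measureRdpDuration
#' @param window_s Post-offset observation window (s).
#' @return Integer count.
#' @export
countReboundOscillations <- function(trace, protocol, threshold_mV = 10,
                                     window_s = 20) {
  stopifnot(is(trace, "VoltageTrace"), is(protocol, "StepProtocol"))
  fs <- trace@fs
  dur <- length(trace@v_mV) / fs
  if (dur - protocol@t_off < window_s - 1e-9)
    stop(sprintf("need >= %g s after the step offset (got %.1f s)",
                 window_s, dur - protocol@t_off))
  v <- lowpass10Hz(trace)@v_mV
  bw <- .baselineWindow(trace, protocol)
  baseline <- mean(v[bw[1]:bw[2]])
  i0 <- .idx(protocol@t_off, fs)
  i1 <- min(length(v), .idx(protocol@t_off + window_s, fs))
  exc <- .excursions(v[i0:i1], fs, baseline + threshold_mV)
  as.integer(exc$n)
}

#' Extract the classification features of one model cell
#'
#' Convenience wrapper for cohort pipelines: simulates the hyperpolarizing
#' RDP protocol and the +100 pA depolarizing step for a cell and returns
#' the two classification features (RDP duration, frequency adaptation
#' index) plus supporting measurements.
#'
#' @param params A [ModelParams-class] object.
#' @param rdp_protocol Hyperpolarizing protocol (default -100 pA, 1 s, with
#'   a 10 s post-offset window).
#' @param depol_protocol Depolarizing protocol (default +100 pA, 1 s).
#' @param fs Sampling rate (Hz).
#' @return One-row data.frame: `rdp_ms`, `rdp_censored`, `rdp_peak_mV`,
#'   `fai`, `fai_defined`, `n_spikes_100pA`.
#' @export
cellFeatures <- function(params,
                         rdp_protocol = stepProtocol(amp_pA = -100),
                         depol_protocol = stepProtocol(amp_pA = 100,
                                                       t_total = 2.5),
                         fs = 20000) {
  tr_h <- simulateCell(params, rdp_protocol, fs = fs)
  rdp <- measureRdpDuration(tr_h, rdp_protocol)
  tr_d <- simulateCell(params, depol_protocol, fs = fs)
  sp <- detectSpikes(tr_d)
  fai <- frequencyAdaptationIndex(sp, depol_protocol)
  data.frame(rdp_ms = rdp$rdp_ms, rdp_censored = rdp$censored,
             rdp_peak_mV = rdp$peak_mV, fai = fai$fai,
             fai_defined = fai$defined,
             n_spikes_100pA = sum(sp$time_s >= depol_protocol@t_on &
                                    sp$time_s < depol_protocol@t_off))
}
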