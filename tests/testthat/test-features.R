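test_that("spike detection finds constructed events and nothing on flat traces", {
  flat <- voltageTrace(rep(-60, 4000), fs = 1000)
  expect_identical(nrow(detectSpikes(flat)), 0L)

  times <- c(0.3, 0.5, 0.9, 1.2, 1.7, 2.1, 2.6)
  tr <- make_spike_train_trace(times, fs = 10000)
  sp <- detectSpikes(tr)
  expect_identical(nrow(sp), 7L)
  expect_equal(sp$time_s, times, tolerance = 1.01 / samplingRate(tr))
  expect_equal(sp$amp_mV, rep(70, 7), tolerance = 1e-6)
  expect_true(all(diff(sp$time_s) > 0))
})

test_that("frequency adaptation index follows its printed definition", {
  pr <- stepProtocol(amp_pA = 100)
  mk <- function(ts) data.frame(time_s = ts, peak_mV = 0, amp_mV = 60)
  # perfectly regular 10 Hz train spanning the step
  reg <- mk(pr@t_on + seq(0.05, 0.95, by = 0.1))
  expect_equal(frequencyAdaptationIndex(reg, pr)$fai, 0)
  # spikes only in the first 300 ms -> empty final window
  early <- mk(pr@t_on + c(0.01, 0.05, 0.12, 0.25))
  expect_equal(frequencyAdaptationIndex(early, pr)$fai, 1)
  # hand-evaluated mixed train: f_init 50 Hz, f_final 5 Hz
  hand <- mk(pr@t_on + c(0.01, 0.03, 0.07, 0.15, 0.31, 0.63, 0.95))
  f <- frequencyAdaptationIndex(hand, pr)
  expect_equal(f$f_init_Hz, 50)
  expect_equal(f$f_final_Hz, 5)
  expect_equal(f$fai, 0.9)
  # undefined below two spikes: explicit flag, not silent NaN
  u <- frequencyAdaptationIndex(mk(pr@t_on + 0.2), pr)
  expect_false(u$defined)
  expect_true(is.na(u$fai))
  # invariance to uniform time translation
  shift <- mk(pr@t_on + c(0.01, 0.03, 0.07, 0.15, 0.31, 0.63, 0.95) + 0)
  pr2 <- stepProtocol(amp_pA = 100, t_on = 3, t_off = 4, t_total = 12)
  shifted <- mk(3 + c(0.01, 0.03, 0.07, 0.15, 0.31, 0.63, 0.95))
  expect_equal(frequencyAdaptationIndex(shifted, pr2)$fai, 0.9)
})

test_that("amplitude adaptation index divides second by first spike amplitude", {
  pr <- stepProtocol(amp_pA = 100)
  mk <- function(amps) data.frame(time_s = pr@t_on + c(0.1, 0.3),
                                  peak_mV = amps - 60, amp_mV = amps)
  expect_equal(amplitudeAdaptationIndex(mk(c(60, 60)), pr)$aai, 1)
  expect_equal(amplitudeAdaptationIndex(mk(c(60, 30)), pr)$aai, 0.5)
  one <- data.frame(time_s = pr@t_on + 0.1, peak_mV = 0, amp_mV = 60)
  expect_false(amplitudeAdaptationIndex(one, pr)$defined)
})

test_that("maximum spike count scans the full 20-100 pA series", {
  counts <- c(2, 5, 9, 7, 4)
  prs <- lapply(seq(20, 100, 20), function(a)
    stepProtocol(amp_pA = a, t_on = 0.5, t_off = 1.5, t_total = 2))
  trs <- lapply(counts, function(k)
    make_spike_train_trace(0.5 + seq_len(k) * 0.1, fs = 5000, t_total = 2))
  expect_identical(maxSpikes(trs, prs), 9L)
  silent <- lapply(counts, function(k) voltageTrace(rep(-60, 10000), fs = 5000))
  expect_identical(maxSpikes(silent, prs), 0L)
  expect_error(maxSpikes(trs[1:3], prs[1:3]), "missing step amplitude")
})

test_that("sag ratio compares peak and steady hyperpolarizing deflections", {
  fs <- 1000
  pr <- stepProtocol(amp_pA = -100, t_on = 1, t_off = 2, t_total = 3)
  v <- rep(-60, 3 * fs)
  tt <- seq(0, 3 - 1 / fs, by = 1 / fs)
  in_step <- tt >= 1 & tt < 2
  # exponential relaxation from -100 (peak 40) to -90 (steady 30)
  v[in_step] <- -90 - 10 * exp(-(tt[in_step] - 1) / 0.05)
  tr <- voltageTrace(v, fs = fs)
  expect_equal(sagRatio(tr, pr), 0.25, tolerance = 0.01)
  v2 <- v; v2[in_step] <- -90
  expect_identical(sagRatio(voltageTrace(v2, fs = fs), pr), 0)
  expect_error(sagRatio(tr, stepProtocol(amp_pA = 100, t_total = 3)),
               "hyperpolarizing")
  # baseline-shift invariance
  expect_equal(sagRatio(voltageTrace(v + 7, fs = fs), pr),
               sagRatio(tr, pr), tolerance = 1e-12)
})

test_that("sag requires the H conductance in the simulator", {
  pr <- stepProtocol(amp_pA = -100, t_total = 4)
  with_h <- sagRatio(simulateCell(modelParams("sag"), pr), pr)
  no_h <- sagRatio(simulateCell(modelParams("short_rdp", g_H = 0), pr), pr)
  expect_gt(with_h, 0.1)
  expect_lt(no_h, 0.02)
})

test_that("RDP duration measurement matches constructed crossings", {
  pr <- stepProtocol(amp_pA = -100, t_on = 1, t_off = 2, t_total = 8)
  # flat after offset -> no RDP
  flat <- make_trapezoid_trace(height = 4)
  m0 <- measureRdpDuration(flat, pr)
  expect_identical(m0$rdp_ms, 0)
  # 15 mV trapezoid from t_off+0.1 to t_off+0.6 -> 500 ms within 5%
  hump <- make_trapezoid_trace(height = 15, hump_from = 2.1, hump_to = 2.6)
  m1 <- measureRdpDuration(hump, pr)
  expect_equal(m1$rdp_ms, 500, tolerance = 0.05 * 500)
  expect_false(m1$censored)
  # never returning below threshold -> censored at trace end
  cens <- make_trapezoid_trace(height = 15, hump_from = 2.1, hump_to = 8.2)
  m2 <- measureRdpDuration(cens, pr)
  expect_true(m2$censored)
  expect_gt(m2$rdp_ms, 5000)
  # guards
  expect_error(measureRdpDuration(flat, stepProtocol(amp_pA = 50, t_total = 8)),
               "hyperpolarizing")
  short_tr <- make_trapezoid_trace(t_total = 4, height = 4)
  expect_error(measureRdpDuration(short_tr, stepProtocol(amp_pA = -100,
                                                         t_total = 4)),
               "beyond the step offset")
  expect_identical(
    measureRdpDuration(short_tr, stepProtocol(amp_pA = -100, t_total = 4),
                       min_post_s = 2)$rdp_ms, 0)
})

test_that("passive properties flag zero-amplitude steps and reject spikes", {
  pr0 <- stepProtocol(amp_pA = 0, t_on = 0.6, t_off = 1.6, t_total = 2)
  tr <- voltageTrace(rep(-58, 2000), fs = 1000)
  pp <- passiveProperties(tr, pr0)
  expect_equal(pp$rmp_mV, -58)
  expect_false(pp$defined)
  spiky <- make_spike_train_trace(1.0, fs = 1000, t_total = 2)
  expect_error(passiveProperties(spiky,
                                 stepProtocol(amp_pA = -10, t_on = 0.6,
                                              t_off = 1.6, t_total = 2)),
               "spikes")
})

test_that("spontaneous activity is classified by rate and burst structure", {
  fs <- 1000
  # 3 spikes in 20 s = 0.15 Hz -> silent
  sil <- make_spike_train_trace(c(3, 9, 16), fs = fs, t_total = 20)
  cs <- classifySpontaneous(sil)
  expect_identical(cs$spont_class, "silent")
  expect_equal(cs$spont_rate_Hz, 0.15)
  # regular 5 Hz, no bursts -> tonic
  ton <- make_spike_train_trace(seq(0.2, 19.8, by = 0.2), fs = fs, t_total = 20)
  expect_identical(classifySpontaneous(ton)$spont_class, "tonic")
  expect_error(classifySpontaneous(make_spike_train_trace(1, fs = fs,
                                                          t_total = 5)),
               "unstimulated recording")
  # simulator burst-mode cell: clustered spikes on depolarizing waves
  pr_rest <- stepProtocol(hold_mV = NA, amp_pA = 0, t_on = 1, t_off = 2,
                          t_total = 22)
  bur <- classifySpontaneous(
    simulateCell(modelParams(c("long_rdp", "burst"), seed = 3), pr_rest))
  expect_identical(bur$spont_class, "burst")
  expect_gt(bur$spont_rate_Hz, 0.2)
})

test_that("rebound oscillation count equals the excursion count of the humps", {
  fs <- 500
  pr <- stepProtocol(amp_pA = -100, t_on = 1, t_off = 2, t_total = 23)
  tt <- seq(0, 23 - 1 / fs, by = 1 / fs)
  v <- rep(-60, length(tt))
  v[tt >= 1 & tt < 2] <- -80
  for (k in 1:12) {
    c0 <- 2.5 + (k - 1) * 1.5
    in_h <- tt >= c0 & tt < c0 + 0.5
    v[in_h] <- -45
  }
  tr <- voltageTrace(v, fs = fs)
  expect_identical(countReboundOscillations(tr, pr), 12L)
  flat <- voltageTrace(rep(-60, length(tt)), fs = fs)
  expect_identical(countReboundOscillations(flat, pr), 0L)
  expect_error(countReboundOscillations(voltageTrace(rep(-60, 10 * fs),
                                                     fs = fs), pr),
               "after the step offset")
})

test_that("spontaneous depolarization durations track evoked RDP durations", {
  # mixed burst-mode cohort: the evoked RDP and the spontaneous
  # depolarization share mechanisms, so their durations correlate
  pr_rest <- stepProtocol(hold_mV = NA, amp_pA = 0, t_on = 1, t_off = 2,
                          t_total = 22)
  pr_rdp <- stepProtocol(amp_pA = -100, t_total = 10)
  cells <- c(lapply(c(3, 5, 7), function(s)
               modelParams(c("short_rdp", "burst"), seed = s)),
             lapply(c(3, 5, 7), function(s)
               modelParams(c("long_rdp", "burst"), seed = s)))
  spont <- vapply(cells, function(p)
    classifySpontaneous(simulateCell(p, pr_rest))$spont_depol_ms, numeric(1))
  rdp <- vapply(cells, function(p) {
    q <- setParams(p, noise_sigma = 0, E_leak_n = -60)
    measureRdpDuration(simulateCell(q, pr_rdp), pr_rdp)$rdp_ms
  }, numeric(1))
  expect_gt(correlations(spont, rdp, "pearson")$estimate, 0.5)
})
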