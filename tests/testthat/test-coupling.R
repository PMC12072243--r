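make_pair <- function(post_fun, fs = 1000, t_total = 6) {
  tt <- seq(0, t_total - 1 / fs, by = 1 / fs)
  pre <- -60 - 30 * (tt >= 1 & tt < 2) + 5 * sin(2 * pi * 0.25 * tt) +
    0.3 * tt
  pmeta <- list(protocol = list(hold_mV = -60, amp_pA = -100, t_on = 1,
                                t_off = 2, t_total = t_total, dt = 1))
  new("PairedTraces",
      pre = voltageTrace(pre, fs = fs, meta = pmeta),
      post = voltageTrace(post_fun(pre), fs = fs, meta = pmeta),
      n_sweeps = 4)
}

test_that("synchrony is rank-based: scaling and sign flips behave exactly", {
  pr <- stepProtocol(amp_pA = -100, t_on = 1, t_off = 2, t_total = 6)
  att <- make_pair(function(v) -80 + 0.1 * (v + 60))
  s1 <- synchrony(att, pr, filter = FALSE)
  expect_equal(s1$rho, 1, tolerance = 1e-9)
  expect_true(s1$coupled)
  inv <- make_pair(function(v) -80 - 0.1 * (v + 60))
  s2 <- synchrony(inv, pr, filter = FALSE)
  expect_equal(s2$rho, -1, tolerance = 1e-9)
  expect_false(s2$coupled)
  # invariance to a strictly increasing transform of one trace
  mono <- make_pair(function(v) -80 + 0.001 * (v + 100)^2)
  expect_equal(synchrony(mono, pr, filter = FALSE)$rho, 1, tolerance = 1e-9)
})

test_that("simulated pairs are synchronized only through the gap junction", {
  pr <- stepProtocol(amp_pA = -200, t_total = 6)
  coupled <- simulatePair(modelParams("long_rdp"), pr)
  expect_gt(synchrony(coupled, pr)$rho, 0.8)
  rho0 <- vapply(1:5, function(s) {
    p <- modelParams("long_rdp", g_gap = 0, noise_sigma = 5, seed = s)
    synchrony(simulatePair(p, pr), pr)$rho
  }, numeric(1))
  expect_true(all(abs(rho0) < 0.3))
})

test_that("post-junctional deflections are small but their rebound ratio is larger", {
  pr <- stepProtocol(amp_pA = -200, t_total = 8)
  pair <- simulatePair(modelParams("long_rdp"), pr)
  pre <- preTrace(pair); post <- postTrace(pair)
  fs <- samplingRate(pre)
  bw <- round(0.5 * fs):round(1.0 * fs)
  sw <- round(1.2 * fs):round(1.9 * fs)
  defl <- function(tr) mean(voltage(tr)[bw]) - min(voltage(tr)[sw])
  expect_gt(defl(post), 0.5)                       # synchronized deflection
  expect_lt(defl(post) / defl(pre), 0.3)           # strongly attenuated
  expect_gt(amplitudeRatio(post, pr), amplitudeRatio(pre, pr))
  # no transmission at all without the gap junction
  flat <- simulatePair(modelParams("long_rdp", g_gap = 0), pr)
  expect_lt(defl(postTrace(flat)), 0.5)
})

test_that("amplitude ratio follows its definition on constructed traces", {
  fs <- 1000
  pr <- stepProtocol(amp_pA = -100, t_on = 1, t_off = 2, t_total = 6)
  tt <- seq(0, 6 - 1 / fs, by = 1 / fs)
  v <- rep(-60, length(tt))
  v[tt >= 1 & tt < 2] <- -80                        # 20 mV hyperpolarization
  v[tt >= 2.2 & tt < 2.7] <- -55                    # 5 mV rebound
  expect_equal(amplitudeRatio(voltageTrace(v, fs = fs), pr, filter = FALSE),
               0.25, tolerance = 1e-9)
  v2 <- v; v2[tt >= 2.2] <- -60                     # no rebound
  expect_identical(amplitudeRatio(voltageTrace(v2, fs = fs), pr,
                                  filter = FALSE), 0)
  v3 <- rep(-60, length(tt))                        # no deflection at all
  expect_error(amplitudeRatio(voltageTrace(v3, fs = fs), pr, filter = FALSE),
               "no hyperpolarizing deflection")
})

test_that("dye positivity criteria apply their strict thresholds per channel", {
  row <- function(nb, ax) data.frame(nb_mean = nb, alexa_mean = ax,
                                     nb_surround_mean = 100, nb_surround_sd = 20,
                                     alexa_surround_mean = 100,
                                     alexa_surround_sd = 20,
                                     is_recorded_cell = FALSE)
  expect_true(dyePositive(row(150, 105))$nb_positive)    # 150 > 140
  expect_false(dyePositive(row(139, 105))$nb_positive)   # 139 < 140
  expect_false(dyePositive(row(140, 105))$nb_positive)   # boundary: strict
  d <- dyePositive(row(150, 105))
  expect_true(d$alexa_negative)                          # 105 < 110
  expect_true(d$coupled)
  dp <- dyePositive(row(150, 130))
  expect_true(dp$excluded)                               # double positive
  expect_false(dp$coupled)
  rec <- row(150, 105); rec$is_recorded_cell <- TRUE
  expect_false(dyePositive(rec)$coupled)                 # the recorded cell
  expect_error(dyePositive(data.frame(nb_mean = 1)), "missing ROI channel")
})

test_that("dye decisions are invariant to per-channel intensity rescaling", {
  roi <- makeRoiFixture(6, 4, 2, seed = 3)
  base <- dyePositive(roi)
  sc <- roi
  for (cc in c("nb_mean", "nb_surround_mean", "nb_surround_sd"))
    sc[[cc]] <- sc[[cc]] * 7.3
  for (cc in c("alexa_mean", "alexa_surround_mean", "alexa_surround_sd"))
    sc[[cc]] <- sc[[cc]] * 0.2
  resc <- dyePositive(sc)
  expect_identical(base$coupled, resc$coupled)
  expect_identical(base$excluded, resc$excluded)
})

test_that("coupling summaries aggregate fixtures and detect a count reduction", {
  tabs <- lapply(1:6, function(s) makeRoiFixture(s %% 3, 2, 1, seed = s))
  sm <- couplingSummary(tabs)
  truth <- vapply(tabs, function(d) sum(d$true_label == "coupled"), numeric(1))
  expect_identical(sm$coupled_counts, truth)
  expect_equal(sm$incidence_pct, 100 * mean(truth >= 1))
  # carbenoxolone-style design: coupled counts forced down in one condition
  ctrl <- lapply(1:8, function(s) makeRoiFixture(4 + s %% 3, 2, 0, seed = 10 + s))
  carb <- lapply(1:8, function(s) makeRoiFixture(s %% 2, 2, 0, seed = 20 + s))
  cmp <- couplingSummary(c(ctrl, carb),
                         condition = rep(c("control", "carb"), each = 8))
  expect_lt(cmp$test$p.value, 0.05)
  expect_error(couplingSummary(list()), "empty input")
})

test_that("marker fractions among coupled cells are computed from fixtures", {
  roi <- makeRoiFixture(10, 3, 2, seed = 5)
  roi$neun <- FALSE
  roi$neun[roi$true_label == "coupled"][1:2] <- TRUE
  sm <- couplingSummary(list(roi), markers = "neun")
  expect_equal(unname(sm$marker_pct["neun"]), 20)
  expect_equal(markerFraction(7, 37), 100 * 7 / 37)
  expect_error(markerFraction(5, 4), "n_total")
})
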