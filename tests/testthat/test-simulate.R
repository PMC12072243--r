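test_that("passive sanity: leak-only cell sits at its leak reversal and is Ohmic", {
  leak_only <- modelParams("short_rdp", g_Na = 0, g_K = 0, g_T = 0,
                           g_SK = 0, g_adapt = 0, g_H = 0, g_gap = 0)
  pr0 <- stepProtocol(amp_pA = 0, t_on = 0.6, t_off = 1.5, t_total = 2)
  tr <- simulateCell(leak_only, pr0)
  expect_true(all(abs(voltage(tr) - (-60)) < 0.1))

  pr <- stepProtocol(amp_pA = -10, t_on = 0.6, t_off = 1.6, t_total = 2)
  tr <- simulateCell(leak_only, pr)
  fs <- samplingRate(tr)
  steady <- mean(voltage(tr)[round(1.5 * fs):round(1.6 * fs)])
  expect_equal(steady - (-60), -5, tolerance = 0.01)   # dV = I/g
  pp <- passiveProperties(tr, pr)
  expect_equal(pp$r_in_MOhm, 500, tolerance = 0.01)
})

test_that("simulation is deterministic and rejects bad input", {
  p <- modelParams("burst", seed = 9)
  pr <- stepProtocol(hold_mV = NA, amp_pA = 0, t_on = 0.5, t_off = 1,
                     t_total = 2)
  a <- simulateCell(p, pr)
  b <- simulateCell(p, pr)
  expect_identical(voltage(a), voltage(b))

  expect_error(stepProtocol(amp_pA = -100, dt = 0),
               "dt must be > 0")
  expect_error(stepProtocol(t_on = 2, t_off = 1), "t_on < t_off")
  expect_error(simulateCell(modelParams("short_rdp"),
                            stepProtocol(amp_pA = -1e5, t_total = 3)),
               "divergence")
})

test_that("drug application is a pure, validated parameter transformation", {
  p <- modelParams("long_rdp")
  q <- applyDrug(p, "ttx")
  expect_identical(param(q, "g_Na"), 0)
  expect_identical(param(p, "g_Na"), 1200)          # input untouched
  others <- setdiff(lhbRDP:::.paramNames(), "g_Na")
  expect_identical(p@values[others], q@values[others])
  expect_identical(param(applyDrug(p, "apamin"), "g_SK"), 0)
  expect_identical(param(applyDrug(p, "z944"), "g_T"), 0)
  expect_identical(param(applyDrug(p, "z944"), "g_T_g"), 0)
  expect_identical(param(applyDrug(p, "lcd"), "g_CNG"), 0)
  expect_identical(param(applyDrug(p, "carbenoxolone"), "g_gap"), 0)
  expect_identical(param(applyDrug(p, "mfa"), "g_gap"), 0)
  expect_identical(param(applyDrug(p, "bapta"), "sk_ca_coupling"), 0)
  expect_lt(param(applyDrug(p, "br_cgmp"), "beta"), param(p, "beta"))
  expect_lt(param(applyDrug(p, "ni_low"), "g_CNG"), param(p, "g_CNG"))
  expect_error(applyDrug(p, "aspirin"), "unknown drug")
})

test_that("model parameter validity and presets behave", {
  expect_error(modelParams("short_rdp", g_T = -1), "conductances")
  expect_error(modelParams("short_rdp", C_n = 0), "capacitances")
  expect_error(modelParams("nonsense"), "unknown phenotype")
  expect_error(setParams(modelParams(), g_bogus = 1), "unknown model parameter")
  lg <- modelParams("long_rdp")
  expect_gt(param(lg, "g_CNG"), 0)
  expect_gt(param(lg, "g_T_g"), 0)
  expect_identical(param(modelParams("short_rdp"), "g_CNG"), 0)
})

test_that("cohort generation realizes the configured phenotype probabilities", {
  co0 <- makeCohort(cohortConfig("a", n_cells = 100, p_long = 0, seed = 1))
  expect_identical(sum(co0$manifest$true_rdp == "long"), 0L)
  co1 <- makeCohort(cohortConfig("b", n_cells = 100, p_long = 1, seed = 1))
  expect_identical(sum(co1$manifest$true_rdp == "long"), 100L)
  coA <- makeCohort(cohortConfig("c", n_cells = 30, p_long = 0.4, seed = 7))
  coB <- makeCohort(cohortConfig("c", n_cells = 30, p_long = 0.4, seed = 7))
  expect_identical(coA$manifest, coB$manifest)
  expect_identical(lapply(coA$params, slot, "values"),
                   lapply(coB$params, slot, "values"))
  # long-labelled cells carry the plateau machinery, short ones do not
  gl <- vapply(coA$params, param, numeric(1), "g_CNG")
  expect_true(all((gl > 0) == (coA$manifest$true_rdp == "long")))
})

test_that("ROI fixture encodes its ground truth and the boundary convention", {
  expect_identical(nrow(makeRoiFixture(0, 0, 0, seed = 1)), 0L)
  roi <- makeRoiFixture(5, 3, 2, seed = 1)
  scored <- dyePositive(roi)
  expect_identical(sum(scored$coupled), 5L)
  expect_identical(scored$coupled, roi$true_label == "coupled")
  expect_identical(sum(scored$excluded), 2L)
  expect_identical(scored$excluded, roi$true_label == "double_positive")
  # margin 0 puts every ROI exactly on its threshold: strict inequalities
  # classify NB as negative and Alexa as non-negative
  b <- dyePositive(makeRoiFixture(4, 2, 1, seed = 2, margin = 0))
  expect_false(any(b$nb_positive))
  expect_false(any(b$coupled))
})
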