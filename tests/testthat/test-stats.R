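test_that("KS statistic behaves at the extremes and matches the reference", {
  same <- ksTwoSample(1:10, 1:10)
  expect_equal(same$D, 0)
  expect_equal(same$p.value, 1)
  expect_equal(ksTwoSample(1:10, 101:110)$D, 1)

  set.seed(31)
  for (rep in 1:5) {
    x <- rnorm(40); y <- rnorm(45, 0.3)
    ours <- ksTwoSample(x, y)
    ref <- ks.test(x, y)
    expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)
  }
  # asymptotic branch (n*m > 1e4)
  x <- rnorm(150); y <- rnorm(150, 0.2)
  ours <- ksTwoSample(x, y)
  ref <- ks.test(x, y)
  expect_false(ours$exact)
  expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)
  expect_error(ksTwoSample(numeric(0), 1:3), "non-empty")
})

test_that("KS D is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rexp(30); y <- rexp(25, 0.7)
  d0 <- ksTwoSample(x, y)$D
  expect_equal(ksTwoSample(log(x), log(y))$D, d0, tolerance = 1e-12)
  expect_equal(ksTwoSample(x^3, y^3)$D, d0, tolerance = 1e-12)
})

test_that("chi-squared with residuals follows the formulas exactly", {
  r <- chiSquaredResiduals(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$statistic, 20)
  expect_identical(r$df, 1)
  expect_equal(abs(r$residuals), matrix(sqrt(20), 2, 2), tolerance = 1e-12)

  prop <- outer(c(20, 30), c(10, 40)) / 50   # exactly proportional
  rp <- chiSquaredResiduals(prop)
  expect_equal(rp$statistic, 0)
  expect_equal(max(abs(rp$residuals)), 0, tolerance = 1e-12)

  expect_error(chiSquaredResiduals(matrix(c(1, 2, 0, 0), 2)),
               "merge sparse categories")
  expect_error(chiSquaredResiduals(matrix(c(1.5, 2, 3, 4), 2)),
               "integer counts")
})

test_that("adjusted residuals agree with an independent implementation", {
  set.seed(17)
  for (rep in 1:10) {
    tab <- matrix(rpois(6, 15) + 1, nrow = 3)
    ours <- chiSquaredResiduals(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$residuals, unclass(ref$stdres), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    # row/column sums of O - E vanish identically
    expect_equal(rowSums(tab - ours$expected), rep(0, 3), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(colSums(tab - ours$expected), rep(0, 2), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("correlations reproduce closed-form cases and the reference", {
  x <- 1:20
  expect_equal(correlations(x, 2 * x + 1, "pearson")$estimate, 1)
  expect_equal(correlations(x, exp(x / 5), "spearman")$estimate, 1)
  set.seed(8)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  for (m in c("pearson", "spearman")) {
    ours <- correlations(a, b, m)
    ref <- suppressWarnings(cor.test(a, b, method = m, exact = FALSE))
    expect_equal(ours$estimate, unname(ref$estimate), tolerance = 1e-9)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
  }
  expect_error(correlations(rep(1, 5), 1:5), "zero variance")
})

test_that("Holm-Sidak adjustment matches the hand-computed step-down sequence", {
  p <- c(0.01, 0.04, 0.03)
  # ordered: 0.01, 0.03, 0.04 -> 1-(1-p)^(3,2,1), cumulative maxima
  hand_sorted <- cummax(c(1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2, 0.04))
  expect_equal(holmSidak(p), hand_sorted[c(1, 3, 2)], tolerance = 1e-12)
  expect_true(all(holmSidak(runif(10)) <= 1))
})

test_that("group tests handle degenerate and standard designs", {
  z <- groupTests(c(1, 2, 3), values2 = c(1, 2, 3), test = "paired_t")
  expect_equal(z$statistic, 0)
  expect_equal(z$p.value, 1)
  w <- groupTests(c(1, 2, 3, 5), values2 = c(2, 1, 4, 4), test = "wilcoxon")
  expect_true(w$p.value > 0 && w$p.value <= 1)
  set.seed(2)
  vals <- c(rnorm(10), rnorm(10, 2), rnorm(10))
  g <- rep(c("a", "b", "c"), each = 10)
  a <- groupTests(vals, groups = g, test = "anova")
  expect_lt(a$p.value, 0.01)
  expect_identical(nrow(a$posthoc), 3L)
  expect_true(all(a$posthoc$p.adj >= a$posthoc$p.raw - 1e-12))
  expect_error(groupTests(vals[1:5], groups = g[1:5],
                          subject = c(1, 1, 2, 2, 3), test = "rm_anova"),
               "unbalanced")
})

test_that("a susceptible-sized subtype shift is detectable by chi-squared", {
  # design check: cohorts of 43 vs 55 cells with long-RDP probabilities
  # 0.16 vs 0.40 reject independence in most replicates
  set.seed(99)
  hits <- 0
  for (r in 1:500) {
    a <- rbinom(1, 43, 0.16); b <- rbinom(1, 55, 0.40)
    tab <- rbind(c(a, 43 - a), c(b, 55 - b))
    p <- tryCatch(chiSquaredResiduals(tab)$p.value, error = function(e) 1)
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 500, 0.70)
})
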