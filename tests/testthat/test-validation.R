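test_that("multi-step TLVC is the arithmetic sum of yearly measurements", {
  expect_equal(multiStepTLVC(c(0.1, -0.05, 0.2)), 0.25)
  expect_equal(multiStepTLVC(0), 0)
  set.seed(18)
  for (i in 1:10) {
    x <- rnorm(sample(1:6, 1))
    acc <- 0
    for (v in x) acc <- acc + v           # loop oracle
    expect_equal(multiStepTLVC(x), acc, tolerance = 1e-12)
  }
  expect_error(multiStepTLVC(numeric(0)), "empty")
})

test_that("percentage volume changes compound multiplicatively", {
  expect_equal(compoundVolumeChange(c(0, 0, 0)), 0)
  expect_equal(compoundVolumeChange(c(-1, -1)), -1.99)
  expect_equal(compoundVolumeChange(2.5), 2.5)      # single entry unchanged
  expect_error(compoundVolumeChange(c(-100, 2)), "-100")
  set.seed(19)
  for (i in 1:10) {
    x <- runif(4, -3, 3)
    # order invariance
    expect_equal(compoundVolumeChange(x), compoundVolumeChange(rev(x)),
                 tolerance = 1e-12)
  }
  # reduces to the sum to first order for small changes
  small <- c(0.4, -0.3, 0.2, -0.5)
  expect_lt(abs(compoundVolumeChange(small) - sum(small)), 0.01)
})

test_that("the expected yearly lesion volume change scales the lesion
           volume by the annual rate", {
  expect_equal(yearlyLesionVolumeChangeEstimate(1.9), 0.19)
  expect_equal(yearlyLesionVolumeChangeEstimate(2, 0.05), 0.1)
})

test_that("ICC for absolute agreement matches the ANOVA oracle and behaves
           as an absolute-agreement index", {
  x <- c(0.82, 1.95, -0.43, 2.61, 0.07, 1.18)
  y <- c(0.95, 1.80, -0.20, 2.55, 0.33, 1.01)
  r <- iccAbsoluteAgreement(x, y)
  expect_equal(r$estimate, oracleICC(x, y), tolerance = 1e-10)
  # reference implementation of the same table (frozen)
  expect_equal(r$estimate, 0.985863501972056, tolerance = 1e-10)
  expect_equal(round(c(r$lower, r$upper), 2), c(0.91, 1.00))
  # perfect agreement
  expect_equal(iccAbsoluteAgreement(x, x)$estimate, 1, tolerance = 1e-12)
  # a large constant offset is punished relative to the consistency ICC
  yOff <- x + 2
  rOff <- iccAbsoluteAgreement(x, yOff)
  expect_lt(rOff$estimate, oracleConsistencyICC(x, yOff) - 0.2)
  # random tables against the ANOVA mean-squares oracle
  set.seed(20)
  for (i in 1:20) {
    a <- rnorm(6); b <- 0.8 * a + rnorm(6, sd = 0.5)
    expect_equal(iccAbsoluteAgreement(a, b)$estimate, oracleICC(a, b),
                 tolerance = 1e-10)
  }
})

test_that("ICC is symmetric in its arguments and rejects degenerate data", {
  set.seed(21)
  a <- rnorm(8); b <- a + rnorm(8, sd = 0.3)
  expect_equal(iccAbsoluteAgreement(a, b)$estimate,
               iccAbsoluteAgreement(b, a)$estimate, tolerance = 1e-10)
  expect_error(iccAbsoluteAgreement(rep(1, 5), rep(1, 5)), "degenerate")
  expect_error(iccAbsoluteAgreement(1:2, 1:2), "3 pairs")
  expect_error(iccAbsoluteAgreement(c(1, NA, 3), c(1, 2, 3)), "missing")
})

test_that("the transitivity report recovers a known error SD and detects a
           coupled factor", {
  # perfect transitivity
  m <- data.frame(tlvcOneStep = c(0.5, -0.2, 1.1, 0.3),
                  tlvcMultiStep = c(0.5, -0.2, 1.1, 0.3))
  rep0 <- transitivityReport(m)
  expect_equal(rep0$icc$estimate, 1, tolerance = 1e-9)
  expect_equal(rep0$sdOfDifference, 0)
  # simulated cohort: delta_trans ~ N(0, 0.25 mL), n = 300; the SD
  # estimate lies in the chi-square sampling band 0.25 +/- 0.03
  set.seed(22)
  one <- rnorm(300, sd = 1)
  multi <- one + rnorm(300, mean = 0, sd = 0.25)
  repN <- transitivityReport(data.frame(tlvcOneStep = one,
                                        tlvcMultiStep = multi))
  expect_equal(repN$sdOfDifference, 0.25, tolerance = 0.03 / 0.25)
  expect_gt(repN$icc$estimate, 0.9)
  # a factor positively coupled to |delta| comes out significant
  delta <- multi - one
  factors <- data.frame(atrophy = abs(delta) + rnorm(300, sd = 0.05))
  repF <- transitivityReport(data.frame(tlvcOneStep = one,
                                        tlvcMultiStep = multi),
                             factors = factors)
  expect_gt(repF$spearman$rs[1], 0)
  expect_lt(repF$spearman$p[1], 0.05)
})

test_that("the accuracy report gives the mean difference, paired t-test and
           degenerate-variance flag", {
  # identical measurements: zero difference, degenerate variance
  m <- data.frame(tlvcOneStep = c(0.4, 0.9, -0.1, 1.2),
                  manualLvc = c(0.4, 0.9, -0.1, 1.2))
  r0 <- accuracyReport(m)
  expect_equal(r0$meanDifference, 0)
  expect_true(r0$degenerateVariance)
  expect_true(is.na(r0$pairedTP))
  # constant offset without noise: flagged, difference reported
  mOff <- data.frame(tlvcOneStep = m$manualLvc + 0.1, manualLvc = m$manualLvc)
  rOff <- accuracyReport(mOff)
  expect_equal(rOff$meanDifference, 0.1, tolerance = 1e-12)
  expect_true(rOff$degenerateVariance)
  # power at the published scale: offset 0.11 mL, noise SD 0.3 mL, n = 328
  # -> p < 0.001 in at least 95% of seeded replicates
  set.seed(23)
  hits <- 0
  for (i in 1:40) {
    manual <- rnorm(328, sd = 1)
    one <- manual + 0.11 + rnorm(328, sd = 0.3)
    r <- accuracyReport(data.frame(tlvcOneStep = one, manualLvc = manual))
    if (r$pairedTP < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 38)
})
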