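# statistical procedures against brute-force oracles

test_that("z-scoring normalizes and refuses constants", {
  expect_equal(zscorePerTrial(c(1, 2, 3)), c(-1, 0, 1))
  x <- poincareHRV:::.withSeed(23, stats::rnorm(100, 5, 3))
  z <- zscorePerTrial(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(stats::sd(z) - 1), 1e-12)
  expect_error(zscorePerTrial(rep(2, 10)), "zero variance")
  zNa <- zscorePerTrial(c(1, NA, 2, 3))
  expect_true(is.na(zNa[2]))
})

test_that("signed-rank test matches exhaustive enumeration and wilcox.test", {
  pre <- 1:10
  w <- wilcoxonSignedRank(pre, pre + 1)
  expect_equal(w$statistic, 55)
  expect_equal(w$p, 2 / 1024)
  expect_true(w$exact)

  expect_error(wilcoxonSignedRank(pre, pre), "zero")

  # antisymmetric differences: Z ~ 0
  d <- c(1, -1, 2, -2, 3, -3, 4, -4, 5, -5)
  wa <- wilcoxonSignedRank(rep(0, 10), d)
  expect_lt(abs(wa$z), 1e-12)

  # oracle: stats::wilcox.test exact p on tie-free data
  x <- poincareHRV:::.withSeed(24, stats::rnorm(11))
  y <- poincareHRV:::.withSeed(25, x + stats::rnorm(11, 0.5))
  w2 <- wilcoxonSignedRank(x, y)
  ref <- stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)
  expect_equal(w2$p, ref$p.value, tolerance = 1e-12)

  # normal approximation branch agrees with wilcox.test's
  x3 <- poincareHRV:::.withSeed(26, stats::rnorm(30))
  y3 <- x3 + 0.3
  w3 <- wilcoxonSignedRank(x3, y3)
  ref3 <- stats::wilcox.test(y3, x3, paired = TRUE, exact = FALSE,
                             correct = FALSE)
  expect_false(w3$exact)
  expect_equal(w3$p, ref3$p.value, tolerance = 1e-10)

  expect_equal(wilcoxonSignedRank(pre, pre + 1, nComparisons = 4)$alpha,
               0.0125)
})

test_that("Friedman statistic matches the direct rank formula and stats::", {
  m0 <- matrix(rep(1:10, 5), 10, 5)
  f0 <- friedmanStat(m0)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p, 1)

  mOrd <- t(apply(matrix(stats::rnorm(50), 10, 5), 1, sort))
  expect_equal(friedmanStat(mOrd)$statistic, 40) # 12n/(k(k+1)) * sum(...)

  m <- poincareHRV:::.withSeed(27, matrix(stats::rnorm(60), 12, 5))
  f <- friedmanStat(m)
  ref <- stats::friedman.test(m)
  expect_equal(f$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(f$p, ref$p.value, tolerance = 1e-12)
  # invariance under condition relabeling
  expect_equal(friedmanStat(m[, c(3, 1, 5, 2, 4)])$statistic, f$statistic)
})

test_that("Spearman t-approximation enforces the positive-rho rule", {
  x <- seq_len(50)
  s <- spearmanT(x, x + 0)
  expect_equal(s$rho, 1)
  expect_true(s$significant)

  sNeg <- spearmanT(x, -x)
  expect_equal(sNeg$rho, -1)
  expect_false(sNeg$significant) # tiny p but wrong sign

  y <- poincareHRV:::.withSeed(28, stats::rnorm(50))
  sM <- spearmanT(x, y, exclude = x <= 10)
  expect_equal(sM$n, 40)
  ref <- stats::cor.test(x[x > 10], y[x > 10], method = "spearman")
  expect_equal(sM$rho, unname(ref$estimate), tolerance = 1e-12)

  expect_error(spearmanT(rep(1, 20), seq_len(20)), "rank variance")
})

test_that("binomial post hoc is the exact upper tail", {
  expect_equal(binomialPosthoc(16, 16), 2^-16)
  expect_equal(binomialPosthoc(0, 16), 1)
  oracle <- sum(choose(16, 10:16)) / 2^16
  expect_equal(binomialPosthoc(10, 16), oracle)
  expect_error(binomialPosthoc(3, 16, pNull = 1.2), "pNull")
})

test_that("effect magnitude is the post-minus-pre window mean", {
  t <- seq(0, 240, by = 0.5)
  step <- ifelse(t > 120, 1, 0)
  expect_equal(effectMagnitude(step, onset = 120, span = 120, t = t), 1)
  expect_equal(effectMagnitude(rep(3, length(t)), onset = 120, span = 120,
                               t = t), 0)
  # linear ramp: oracle = difference of the two sampled-window means
  ramp <- 0.01 * t
  oracle <- mean(ramp[t > 120 & t <= 240]) - mean(ramp[t >= 0 & t <= 120])
  expect_equal(effectMagnitude(ramp, onset = 120, span = 120, t = t),
               oracle)
  expect_error(effectMagnitude(step, onset = 500, span = 120, t = t),
               "cover")
})

test_that("the robustness harness is deterministic and shaped correctly", {
  ib <- buildIbi(ipfmBeats(coldPressorScenario(seed = 29)))
  res <- robustnessExperiment(ib, onset = 120,
                              methods = list(covMethod("exact")),
                              nRange = c(0, 3), reps = 3, seed = 11)
  eff <- res$exact$effect
  expect_equal(dim(eff), c(3, 2))
  # no randomness without outliers
  expect_equal(unname(eff[, 1]), rep(unname(eff[1, 1]), 3))
  expect_equal(res$exact$madByN[[1]], 0)
  # repeat run is identical
  res2 <- robustnessExperiment(ib, onset = 120,
                               methods = list(covMethod("exact")),
                               nRange = c(0, 3), reps = 3, seed = 11)
  expect_identical(res$exact$effect, res2$exact$effect)
})
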