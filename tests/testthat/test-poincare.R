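# windowed Poincare geometry and the four covariance back-ends

test_that("window extraction matches a brute-force pair scan", {
  ib <- buildIbi(beatAnnotations(seq(0, 60, by = 1)))
  pr <- windowPairs(ib, t = 30, T = 15)
  expect_equal(length(pr@x), 15)
  expect_true(all(pr@x == 1) && all(pr@y == 1))

  expect_length(windowPairs(ib, t = -5, T = 15)@x, 0)

  # O(n^2) oracle on an irregular series
  r <- cumsum(poincareHRV:::.withSeed(5, stats::runif(120, 0.5, 1.3)))
  ibr <- buildIbi(beatAnnotations(r))
  for (t0 in c(20, 47.3, 80)) {
    pr <- windowPairs(ibr, t0, T = 12)
    ora <- NULL
    for (i in seq_len(nBeats(ibr) - 1)) {
      if (ibr@t[i] >= t0 - 12 && ibr@t[i + 1] <= t0)
        ora <- rbind(ora, c(ibr@ibi[i], ibr@ibi[i + 1]))
    }
    if (is.null(ora)) ora <- matrix(numeric(0), 0, 2)
    expect_equal(cbind(pr@x, pr@y), ora, ignore_attr = TRUE)
  }
})

test_that("centroid distance follows the closed forms", {
  mk <- function(x, y) new("LaggedPairs", x = x, y = y, refTime = 0)
  expect_equal(computeCcd(mk(rep(1, 5), rep(1, 5))), sqrt(2))
  expect_equal(computeCcd(mk(rep(0.8, 5), rep(0.8, 5))), 0.8 * sqrt(2))
  expect_equal(computeCcd(mk(c(0.8, 1.0), c(1.1, 1.3))), 1.5) # 3-4-5
  expect_true(is.na(computeCcd(mk(numeric(0), numeric(0)))))
})

test_that("eigenvalue-to-SD assignment follows eigenvector orientation", {
  expect_equal(sdFromCovariance(diag(c(4e-4, 4e-4))),
               c(sd1 = 0.02, sd2 = 0.02))
  d <- 0.03
  covAlt <- matrix(c(d^2, -d^2, -d^2, d^2), 2)
  s <- sdFromCovariance(covAlt)
  expect_equal(s[["sd1"]], d * sqrt(2))
  expect_equal(s[["sd2"]], 0)
  # rank-1 along the identity line: all dispersion is SD2
  covLine <- matrix(c(d^2, d^2, d^2, d^2), 2)
  s2 <- sdFromCovariance(covLine)
  expect_equal(s2[["sd1"]], 0)
  expect_equal(s2[["sd2"]], d * sqrt(2))
  expect_error(sdFromCovariance(matrix(c(1, 0, 0, -1), 2)), "negative")
})

test_that("shrinkage covariance converges to the sample covariance", {
  X <- poincareHRV:::.withSeed(8, {
    z <- matrix(stats::rnorm(2 * 5000), ncol = 2)
    z %*% chol(matrix(c(4e-3, 2e-3, 2e-3, 4e-3), 2))
  })
  pr <- new("LaggedPairs", x = X[, 1] + 0.9, y = X[, 2] + 0.9, refTime = 0)
  Se <- estimateCovariance(pr, covMethod("exact"))
  Sr <- estimateCovariance(pr, covMethod("robust"))
  expect_lt(norm(Sr - Se, "F") / norm(Se, "F"), 0.02)
})

test_that("MCD covariance matches MASS and resists gross outliers", {
  skip_if_not_installed("MASS")
  Xc <- poincareHRV:::.withSeed(9, {
    z <- matrix(stats::rnorm(2 * 100), ncol = 2)
    sweep(z %*% chol(matrix(c(4e-3, 2e-3, 2e-3, 4e-3), 2)), 2, c(0.9, 0.9),
          "+")
  })
  out <- matrix(0.9 + 10 * sqrt(4e-3), 5, 2)
  Xo <- rbind(Xc, out)
  pr <- new("LaggedPairs", x = Xo[, 1], y = Xo[, 2], refTime = 0)
  Smcd <- estimateCovariance(pr, covMethod("p95"))
  Sex <- estimateCovariance(pr, covMethod("exact"))
  Scl <- stats::cov(Xc)
  expect_lt(norm(Smcd - Scl, "F") / norm(Scl, "F"), 0.25)
  expect_gt(norm(Sex, "F") / norm(Scl, "F"), 2)

  # independent oracle: MASS's MCD finds the same optimal subset (equal up
  # to the consistency rescaling, which is scalar)
  h <- round(0.95 * nrow(Xo))
  rob <- MASS::cov.rob(Xo, method = "mcd", quantile.used = h,
                       nsamp = "best")
  expect_equal(Smcd / norm(Smcd, "F"), rob$cov / norm(rob$cov, "F"),
               tolerance = 1e-6)
})

test_that("p95 output ignores up to 5% arbitrary replacements", {
  ib <- stationaryIbi(200, seed = 10)
  v <- ibiValues(ib)
  pr <- new("LaggedPairs", x = v[-length(v)], y = v[-1], refTime = 0)
  S0 <- estimateCovariance(pr, covMethod("p95"))
  vBad <- v
  bad <- c(40, 80, 120, 160) # 4 values -> 8 of 199 pairs (~4%) contaminated
  vBad[bad] <- vBad[bad] + 0.5 # far outside the bulk
  prB <- new("LaggedPairs", x = vBad[-length(vBad)], y = vBad[-1],
             refTime = 0)
  SB <- estimateCovariance(prB, covMethod("p95"))
  SE <- estimateCovariance(prB, covMethod("exact"))
  expect_lt(norm(SB - S0, "F") / norm(S0, "F"), 0.5)
  expect_gt(norm(SE - S0, "F") / norm(S0, "F"), 1.5)
})

test_that("approximate SDs agree with the eigen route", {
  expect_equal(sdApproximate(rep(0.9, 20)), c(sd1 = 0, sd2 = 0))

  # alternating m +/- d: both routes give SD1 = d*sqrt(2)*k, SD2 ~ 0
  d <- 0.02
  w <- 0.9 + d * (-1)^(seq_len(400))
  sA <- sdApproximate(w)
  pr <- new("LaggedPairs", x = w[-length(w)], y = w[-1], refTime = 0)
  sE <- sdFromCovariance(estimateCovariance(pr, covMethod("exact")))
  expect_equal(sA[["sd1"]], sE[["sd1"]], tolerance = 0.01)
  expect_equal(sA[["sd1"]], d * sqrt(2), tolerance = 0.01)
  expect_lt(sE[["sd2"]], 0.1 * sE[["sd1"]])

  # white noise: gamma1 = 0, so sd1 ~ sd2 ~ sigma
  w2 <- poincareHRV:::.withSeed(11, 0.9 + stats::rnorm(5000, 0, 0.03))
  s2 <- sdApproximate(w2)
  expect_equal(s2[["sd1"]], 0.03, tolerance = 0.05)
  expect_equal(s2[["sd2"]], 0.03, tolerance = 0.05)
})

test_that("AR(1) series reproduce the analytic SD limits", {
  phi <- 0.5; sigma <- 0.02
  ib <- ar1Ibi(5000, phi, sigma, seed = 3)
  ga <- globalAnchors(ib, covMethod("exact"))
  g0 <- sigma^2 / (1 - phi^2); g1 <- phi * g0
  expect_equal(ga@sd01, sqrt(g0 - g1), tolerance = 0.03)
  expect_equal(ga@sd02, sqrt(g0 + g1), tolerance = 0.03)
})

test_that("descriptor series match closed forms and handle sparse windows", {
  ib <- buildIbi(beatAnnotations(seq(0, 60, by = 1)))
  d <- descriptorSeries(ib, T = 15, method = covMethod("exact"))
  ok <- !is.na(d@ccd)
  expect_true(any(ok))
  expect_true(all(abs(d@ccd[ok] - sqrt(2)) < 1e-12))
  expect_true(all(d@sd1[ok] == 0) && all(d@sd2[ok] == 0))
  # per-beat grid: one evaluation per interval anchor
  expect_length(d@t, nBeats(ib))
  expect_error(descriptorSeries(ib, T = 100), "exceed")

  # SD2 >= SD1 on positively lag-correlated series. Exactly: whenever the
  # window's sample lag-covariance is positive the orientation assignment
  # must put the larger eigenvalue on SD2 (never swapped); overall, the
  # dominance holds in the large majority of windows for every method
  # (finite 15 s windows occasionally sample a negative lag-covariance).
  for (seed in 1:5) {
    ib2 <- ar1Ibi(400, 0.6, 0.02, seed = seed)
    dE <- descriptorSeries(ib2, T = 15, method = covMethod("exact"))
    v2 <- ibiValues(ib2); t2 <- seriesTimes(ib2)
    for (k in which(!is.na(dE@sd1))) {
      i <- which(t2 >= dE@t[k] - 15 & t2 <= dE@t[k])
      i <- i[-length(i)]
      if (stats::cov(v2[i], v2[i + 1]) > 0)
        expect_gte(dE@sd2[k], dE@sd1[k])
    }
    for (m in c("exact", "robust", "p95", "approximate")) {
      dd <- descriptorSeries(ib2, T = 15, method = covMethod(m))
      ok <- !is.na(dd@sd1)
      expect_gt(mean(dd@sd2[ok] >= dd@sd1[ok]), 0.85)
    }
  }
})

test_that("a step in mean IBI moves CCD but not SD1", {
  cfg <- coldPressorScenario(seed = 12)
  ib <- buildIbi(ipfmBeats(cfg))
  d <- descriptorSeries(ib, T = 15, method = covMethod("exact"))
  pre <- d@t > 20 & d@t <= 120
  post <- d@t > 140 # skip the window straddling the step
  expect_lt(mean(d@ccd[post], na.rm = TRUE), mean(d@ccd[pre], na.rm = TRUE))
})
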