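# IPFM generator, template ECG, ectopic injection, cohorts

test_that("the IPFM generator hits its configured rate and spectrum", {
  b <- ipfmBeats(scenarioConfig(duration = 60, baseRate = 1, aLf = 0,
                                aHf = 0, noiseSd = 0))
  expect_true(all(abs(ibiValues(buildIbi(b)) - 1) < 1e-9))

  bLong <- ipfmBeats(scenarioConfig(duration = 600, baseRate = 1.2,
                                    noiseSd = 0))
  rate <- (nBeats(bLong) - 1) / diff(range(beatTimes(bLong)))
  expect_equal(rate, 1.2, tolerance = 0.01)

  # HF modulation shows up at its frequency in the IBI spectrum
  bHf <- ipfmBeats(scenarioConfig(duration = 300, aLf = 0, aHf = 0.1,
                                  fHf = 0.25, noiseSd = 0))
  u <- resampleUniform(buildIbi(bHf), fs = 4)
  v <- u@values - mean(u@values)
  f <- (seq_along(v) - 1) * 4 / length(v)
  half <- f <= 2 & f > 0.02
  expect_equal(f[half][which.max(Mod(stats::fft(v))[half]^2)], 0.25,
               tolerance = 0.01)

  # a 25% rate step scales mean IBI by ~1/1.25
  bStep <- ipfmBeats(scenarioConfig(duration = 240, transitionTime = 120,
                                    postRateFactor = 1.25, noiseSd = 0))
  ib <- buildIbi(bStep)
  pre <- mean(ibiValues(ib)[seriesTimes(ib) <= 120])
  post <- mean(ibiValues(ib)[seriesTimes(ib) > 121])
  expect_equal(post / pre, 0.8, tolerance = 0.01)

  expect_error(scenarioConfig(aLf = 0.6, aHf = 0.5), "positive")
  # generators are bit-reproducible
  cfg <- scenarioConfig(duration = 120, seed = 3)
  expect_identical(beatTimes(ipfmBeats(cfg)), beatTimes(ipfmBeats(cfg)))
})

test_that("ectopic injection shifts exactly the chosen beats", {
  b <- ipfmBeats(scenarioConfig(duration = 120, noiseSd = 0, seed = 1))
  spec0 <- ectopicSpec(nOutliers = 0, tLo = 0, tHi = 120)
  expect_identical(beatTimes(injectEctopics(b, spec0)), beatTimes(b))

  spec1 <- ectopicSpec(nOutliers = 1, tLo = 30, tHi = 90, seed = 4)
  b1 <- injectEctopics(b, spec1)
  k <- which(beatTimes(b1) != beatTimes(b))
  expect_length(k, 1)
  expect_equal(beatTimes(b1)[k] - beatTimes(b)[k], 0.030)
  d0 <- diff(beatTimes(b)); d1 <- diff(beatTimes(b1))
  expect_equal(d1[k - 1] - d0[k - 1], 0.030)
  expect_equal(d1[k] - d0[k], -0.030)
  expect_equal(sum(d1), sum(d0), tolerance = 1e-12)
  expect_true(all(d1[-c(k - 1, k)] == d0[-c(k - 1, k)]))

  # deterministic per seed
  expect_identical(beatTimes(injectEctopics(b, spec1)), beatTimes(b1))
  spec2 <- ectopicSpec(nOutliers = 5, tLo = 30, tHi = 90, seed = 5)
  spec3 <- ectopicSpec(nOutliers = 5, tLo = 30, tHi = 90, seed = 6)
  expect_false(identical(beatTimes(injectEctopics(b, spec2)),
                         beatTimes(injectEctopics(b, spec3))))

  expect_error(injectEctopics(b, ectopicSpec(nOutliers = 10, tLo = 0,
                                             tHi = 3)), "eligible")
})

test_that("the ECG template closes the loop with detection and QT", {
  b <- ipfmBeats(scenarioConfig(duration = 60, baseRate = 1, aLf = 0,
                                aHf = 0, noiseSd = 0))
  ecg <- synthEcg(b, fs = 200)
  det <- detectRPeaks(ecg)
  expect_lt(matchBeats(det, b)$maxErr, 0.010)
  qt <- detectQt(ecg, det)
  expect_true(all(abs(qt@qt - 0.390) <= 0.005))

  expect_error(synthEcg(beatAnnotations(seq(0, 5, by = 0.25)), fs = 200),
               "overlap")
})

test_that("cohorts split at the transition and respond as a group", {
  co <- cohort(coldPressorScenario(seed = 21), nSubjects = 18,
               betweenSubjectSd = 0.1)
  expect_length(co, 18)
  for (tr in co[1:3]) {
    expect_true(all(seriesTimes(tr$pre) <= tr$onset))
    expect_true(all(seriesTimes(tr$post) > tr$onset))
    expect_equal(nBeats(tr$pre) + nBeats(tr$post), nBeats(tr$ibi))
  }
  # zero between-subject spread: configs differ only by seed
  co0 <- cohort(coldPressorScenario(seed = 22), nSubjects = 3,
                betweenSubjectSd = 0)
  expect_equal(co0[[1]]$config@baseRate, co0[[2]]$config@baseRate)

  # group medians move the right way through the full index pipeline
  effCsi <- effCpi <- numeric(8)
  for (i in 1:8) {
    idx <- autonomicIndices(co[[i]]$ibi)
    effCsi[i] <- effectMagnitude(idx, onset = co[[i]]$onset, span = 100)
    effCpi[i] <- effectMagnitude(idx, onset = co[[i]]$onset, span = 100,
                                 which = "cpi")
  }
  expect_gt(stats::median(effCsi), 0)
  expect_lt(stats::median(effCpi), 0)
})

test_that("surrogate pressure tracks the index at the requested strength", {
  x <- sin(seq(0, 20, length.out = 400))
  y <- surrogatePressure(seq_along(x), x, rho = 0.9, seed = 2)
  expect_gt(stats::cor(x, y, method = "spearman"), 0.6)
  expect_identical(y, surrogatePressure(seq_along(x), x, rho = 0.9,
                                        seed = 2))
})
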