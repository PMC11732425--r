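# spline resampling, smoothed pseudo Wigner-Ville, band integration

test_that("uniform resampling reproduces smooth signals", {
  t <- cumsum(rep(0.9, 50))
  expect_true(all(resampleUniform(ibiSeries(t, rep(0.8, 50)))@values == 0.8))

  ramp <- ibiSeries(t, 0.5 + 0.001 * t)
  u <- resampleUniform(ramp, fs = 4)
  expect_lt(max(abs(u@values - (0.5 + 0.001 * seriesTimes(u)))), 1e-9)

  # 0.1 Hz sinusoid sampled at ~1 Hz beats: FFT peak lands on 0.1 Hz
  tb <- cumsum(rep(1, 300))
  s <- ibiSeries(tb, 0.9 + 0.05 * sin(2 * pi * 0.1 * tb))
  us <- resampleUniform(s, fs = 4)
  v <- us@values - mean(us@values)
  sp <- Mod(stats::fft(v))^2
  f <- (seq_along(v) - 1) * 4 / length(v)
  half <- f <= 2
  expect_equal(f[half][which.max(sp[half])], 0.1, tolerance = 0.01)

  expect_error(resampleUniform(ibiSeries(c(1, 2), c(1, 1))), "4 points")
})

test_that("the TF map localizes tones and suppresses cross-terms", {
  tg <- seq(0, 300, by = 0.25)
  u <- uniformSeries(sin(2 * pi * 0.1 * tg), fs = 4)
  tf <- pseudoWignerVille(u)
  interior <- which(!tf@burnin)
  peaks <- tf@freq[apply(tf@power[interior, ], 1, which.max)]
  expect_true(all(abs(peaks - 0.1) <= 0.02))

  # two tones: interference at the midpoint frequency is suppressed
  u2 <- uniformSeries(sin(2 * pi * 0.1 * tg) + sin(2 * pi * 0.3 * tg),
                      fs = 4)
  tf2 <- pseudoWignerVille(u2)
  atF <- function(f0) {
    j <- which.min(abs(tf2@freq - f0))
    stats::median(rowMeans(tf2@power[interior, j + (-2:2)]))
  }
  expect_lt(atF(0.2), 0.1 * min(atF(0.1), atF(0.3)))

  # energy: integrated power ~ signal variance (tone: a^2/2 = 0.5)
  df <- tf@freq[2] - tf@freq[1]
  en <- mean(rowSums(tf@power)) * df
  expect_equal(en, 0.5, tolerance = 0.1)

  expect_error(pseudoWignerVille(uniformSeries(stats::rnorm(32), fs = 4)),
               "64 samples")
})

test_that("band powers scale as amplitude squared and shift with time", {
  tg <- seq(0, 240, by = 0.25)
  u <- uniformSeries(0.05 * sin(2 * pi * 0.1 * tg), fs = 4)
  u2 <- uniformSeries(2 * u@values, fs = 4)
  lf1 <- bandPower(pseudoWignerVille(u), c(0.04, 0.15))
  lf2 <- bandPower(pseudoWignerVille(u2), c(0.04, 0.15))
  ok <- !lf1$burnin
  expect_equal(lf2$power[ok], 4 * lf1$power[ok], tolerance = 1e-9)

  # delaying the record shifts the time axis only
  uS <- uniformSeries(u@values, fs = 4, t0 = 37)
  lfS <- bandPower(pseudoWignerVille(uS), c(0.04, 0.15))
  expect_equal(lfS$t, lf1$t + 37)
  expect_equal(lfS$power, lf1$power)

  expect_error(bandPower(pseudoWignerVille(u), c(3, 4)), "outside")
})

test_that("band dominance follows the modulation frequency", {
  tg <- seq(0, 300, by = 0.25)
  frac <- function(fmod) {
    u <- uniformSeries(0.05 * sin(2 * pi * fmod * tg), fs = 4)
    tf <- pseudoWignerVille(u)
    lf <- bandPower(tf, c(0.04, 0.15))
    hf <- bandPower(tf, c(0.15, 0.4))
    ok <- !lf$burnin
    stats::median(lf$power[ok] / (lf$power[ok] + hf$power[ok]))
  }
  expect_gt(frac(0.10), 0.9)
  expect_lt(frac(0.25), 0.1)

  # white noise: LF:HF ratio ~ bandwidth ratio 0.11:0.25; averaged over
  # realizations since a single periodogram fluctuates band to band
  ratios <- vapply(1:6, function(s) {
    uw <- uniformSeries(poincareHRV:::.withSeed(s, stats::rnorm(1200)),
                        fs = 4)
    tfw <- pseudoWignerVille(uw)
    lfw <- bandPower(tfw, c(0.04, 0.15))
    hfw <- bandPower(tfw, c(0.15, 0.4))
    ok <- !lfw$burnin
    stats::median(lfw$power[ok] / hfw$power[ok])
  }, 0)
  expect_equal(mean(ratios), 0.11 / 0.25, tolerance = 0.3)
})

test_that("the QT LF channel equals its three-stage composition", {
  tb <- cumsum(rep(0.9, 300))
  qtConst <- qtSeries(tb, rep(0.39, 300))
  lfConst <- lfQt(qtConst)
  expect_lt(max(lfConst$power), 1e-20)

  qtMod <- qtSeries(tb, 0.39 + 0.01 * sin(2 * pi * 0.1 * tb))
  qtFast <- qtSeries(tb, 0.39 + 0.01 * sin(2 * pi * 0.3 * tb))
  pSlow <- lfQt(qtMod)
  pFast <- lfQt(qtFast)
  ok <- !pSlow$burnin
  expect_gt(stats::median(pSlow$power[ok]),
            10 * stats::median(pFast$power[ok]))

  manual <- bandPower(pseudoWignerVille(resampleUniform(qtMod, fs = 4)),
                      c(0.04, 0.15))
  expect_equal(pSlow$power, manual$power)
})
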