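# shared fixtures, all generated in code

# sensitivity / positive predictivity of detected vs true beat times
matchBeats <- function(detected, truth, tol = 0.05) {
  dt <- beatTimes(detected)
  tt <- beatTimes(truth)
  d <- abs(outer(dt, tt, "-"))
  list(sens = mean(apply(d, 2, min) < tol),
       ppv = mean(apply(d, 1, min) < tol),
       maxErr = max(apply(d, 2, min)))
}

# stationary two-tone IBI series of roughly n intervals
stationaryIbi <- function(n = 500, seed = 0, baseRate = 1.1) {
  cfg <- scenarioConfig(duration = ceiling((n + 2) / baseRate),
                        baseRate = baseRate, seed = seed)
  ib <- buildIbi(ipfmBeats(cfg))
  if (nBeats(ib) > n) ib <- ibiSeries(ib@t[1:n], ib@ibi[1:n])
  ib
}

# AR(1) interbeat series with known autocovariance
ar1Ibi <- function(n, phi, sigma, mean = 0.9, seed = 0) {
  v <- poincareHRV:::.withSeed(seed, {
    e <- stats::rnorm(n, 0, sigma)
    as.numeric(stats::filter(e, phi, method = "recursive")) + mean
  })
  ibiSeries(cumsum(v), v)
}
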