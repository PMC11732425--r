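# Synthetic data with controlled autonomic structure. The IPFM (integral
# pulse frequency modulation) model fires a beat whenever the integral of the
# modulated sinoatrial rate crosses an integer, so the spectral content of
# the resulting IBI series at the LF/HF modulation frequencies is known by
# construction — the property every comparator test needs.

#' Generate beats with an IPFM model
#'
#' The instantaneous rate is
#' \code{r(t) = R(t) * (1 + aLf sin(2 pi fLf t) + aHf(t) sin(2 pi fHf t))},
#' where \code{R(t)} steps from \code{baseRate} to
#' \code{baseRate * postRateFactor} and \code{aHf(t)} to
#' \code{aHf * postAhfFactor} at \code{transitionTime}. Beats fire when the
#' integral of \code{r} crosses successive integers; independent Gaussian
#' jitter of sd \code{noiseSd} is then added to each beat time. Deterministic
#' given the config (including its seed).
#'
#' @param cfg a [ScenarioConfig-class].
#' @param dtIntegration integration step (s) for the rate integral.
#' @return a [BeatAnnotations-class].
#' @export
ipfmBeats <- function(cfg, dtIntegration = 0.005) {
  stopifnot(is(cfg, "ScenarioConfig"))
  tg <- seq(0, cfg@duration, by = dtIntegration)
  post <- if (is.finite(cfg@transitionTime)) tg >= cfg@transitionTime
          else rep(FALSE, length(tg))
  R <- ifelse(post, cfg@baseRate * cfg@postRateFactor, cfg@baseRate)
  ahf <- ifelse(post, cfg@aHf * cfg@postAhfFactor, cfg@aHf)
  r <- R * (1 + cfg@aLf * sin(2 * pi * cfg@fLf * tg) +
              ahf * sin(2 * pi * cfg@fHf * tg))
  if (any(r <= 0))
    stop("rate modulation dips to zero or below; reduce the amplitudes")
  # trapezoidal cumulative integral of the rate
  phi <- c(0, cumsum((r[-1] + r[-length(r)]) / 2 * dtIntegration))
  nb <- floor(phi[length(phi)])
  if (nb < 1) stop("record too short: no beat fires")
  beats <- stats::approx(phi, tg, xout = seq_len(nb))$y
  if (cfg@noiseSd > 0) {
    jit <- .withSeed(cfg@seed, stats::rnorm(nb, 0, cfg@noiseSd))
    beats <- sort(beats + jit)
  }
  beatAnnotations(beats)
}

#' Synthesize a single-lead ECG from beat times
#'
#' Sums a per-beat template of Gaussian bumps (P wave, Q trough, R spike,
#' S trough, T wave and a T-end trough) and optionally adds white noise at a
#' given signal-to-noise ratio. Default template extrema: Q trough at
#' R - 40 ms and T-end trough at R + 350 ms, so the constructed QT interval
#' is 390 ms.
#'
#' @param beats a [BeatAnnotations-class]; mean rate must stay below 3
#'   beats/s so templates do not overlap.
#' @param fs sampling rate (Hz), at least 100.
#' @param snrDb signal-to-noise ratio in dB, or NULL for a clean signal.
#' @param seed integer seed for the noise.
#' @param qOffset,tEndOffset template extremum offsets from the R-peak (s).
#' @return an [EcgSignal-class] starting 0.5 s before the first beat.
#' @export
synthEcg <- function(beats, fs = 200, snrDb = NULL, seed = 0,
                     qOffset = -0.040, tEndOffset = 0.350) {
  stopifnot(is(beats, "BeatAnnotations"))
  if (fs < 100) stop("fs must be at least 100 Hz")
  r <- beats@rTimes
  if (length(r) >= 2 && min(diff(r)) < 1 / 3)
    stop("instantaneous rate above 3 beats/s: templates would overlap")
  t0 <- r[1] - 0.5
  t1 <- r[length(r)] + 0.7
  tg <- seq(t0, t1, by = 1 / fs)
  x <- numeric(length(tg))
  bump <- function(centre, amp, width) {
    lo <- findInterval(centre - 5 * width, tg)
    hi <- findInterval(centre + 5 * width, tg) + 1L
    idx <- max(1L, lo):min(length(tg), hi)
    x[idx] <<- x[idx] + amp * exp(-(tg[idx] - centre)^2 / (2 * width^2))
  }
  for (rt in r) {
    bump(rt - 0.200, 0.10, 0.025)   # P
    bump(rt + qOffset, -0.20, 0.008) # Q trough
    bump(rt, 1.00, 0.008)            # R
    bump(rt + 0.030, -0.15, 0.008)   # S
    bump(rt + 0.250, 0.25, 0.035)    # T
    bump(rt + tEndOffset, -0.12, 0.018) # T-end trough
  }
  if (!is.null(snrDb)) {
    noiseSd <- stats::sd(x) / sqrt(10^(snrDb / 10))
    x <- x + .withSeed(seed, stats::rnorm(length(x), 0, noiseSd))
  }
  ecgSignal(x, fs = fs, t0 = t0)
}

#' Inject ectopic-like timing outliers
#'
#' Shifts \code{nOutliers} randomly selected beats inside the placement
#' window by \code{+delay} seconds. The interval closing at a shifted beat
#' grows by \code{delay}, the next interval shrinks by \code{delay}, and the
#' total record duration is unchanged. First and last beats are never
#' selected. Deterministic per seed; the input is not modified.
#'
#' @param beats a [BeatAnnotations-class].
#' @param spec an [EctopicSpec-class].
#' @return a new [BeatAnnotations-class].
#' @export
injectEctopics <- function(beats, spec) {
  stopifnot(is(beats, "BeatAnnotations"), is(spec, "EctopicSpec"))
  if (spec@nOutliers == 0) return(beats)
  r <- beats@rTimes
  n <- length(r)
  eligible <- which(r >= spec@tLo & r <= spec@tHi)
  eligible <- setdiff(eligible, c(1L, n))
  if (length(eligible) < spec@nOutliers)
    stop("placement window holds only ", length(eligible),
         " eligible beats (need ", spec@nOutliers, ")")
  pick <- .withSeed(spec@seed,
                    sample(eligible, spec@nOutliers, replace = FALSE))
  r[pick] <- r[pick] + spec@delay
  if (is.unsorted(r, strictly = TRUE))
    stop("delay too large: shifted beats cross their neighbours")
  beatAnnotations(r)
}

#' Generate a synthetic cohort of transition trials
#'
#' Per subject, the base rate and modulation amplitudes of \code{cfgBase} are
#' perturbed log-normally with coefficient \code{betweenSubjectSd}, one IPFM
#' record with a single transition is generated, and the resulting IBI series
#' is split at the transition.
#'
#' @param cfgBase a [ScenarioConfig-class] with a finite
#'   \code{transitionTime} (e.g. [coldPressorScenario()]).
#' @param nSubjects number of subjects (>= 2).
#' @param betweenSubjectSd log-normal sd of the between-subject perturbation
#'   (fractional; default 0.1).
#' @return a list of trials; each holds \code{ibi} (full [IbiSeries-class]),
#'   \code{onset}, \code{pre} and \code{post} (the split series) and the
#'   subject's [ScenarioConfig-class].
#' @export
cohort <- function(cfgBase, nSubjects, betweenSubjectSd = 0.1) {
  stopifnot(is(cfgBase, "ScenarioConfig"), nSubjects >= 2)
  if (!is.finite(cfgBase@transitionTime))
    stop("cfgBase must define a transitionTime")
  lapply(seq_len(nSubjects), function(s) {
    pert <- .withSeed(cfgBase@seed + 7919 * s,
                      exp(stats::rnorm(3, 0, betweenSubjectSd)))
    rate <- cfgBase@baseRate * pert[1]
    if (rate < 0.5 || rate > 3)
      stop("perturbed base rate outside [0.5, 3] beats/s for subject ", s)
    cfg <- scenarioConfig(
      duration = cfgBase@duration, baseRate = rate,
      aLf = min(cfgBase@aLf * pert[2], 0.4),
      fLf = cfgBase@fLf,
      aHf = min(cfgBase@aHf * pert[3], 0.4),
      fHf = cfgBase@fHf,
      transitionTime = cfgBase@transitionTime,
      postRateFactor = cfgBase@postRateFactor,
      postAhfFactor = cfgBase@postAhfFactor,
      noiseSd = cfgBase@noiseSd,
      seed = cfgBase@seed + 7919 * s + 1)
    ibi <- buildIbi(ipfmBeats(cfg))
    onset <- cfg@transitionTime
    pre <- ibi@t <= onset
    list(ibi = ibi, onset = onset,
         pre = ibiSeries(ibi@t[pre], ibi@ibi[pre]),
         post = ibiSeries(ibi@t[!pre], ibi@ibi[!pre]),
         config = cfg)
  })
}

#' Surrogate beat-to-beat pressure series correlated with an index
#'
#' Rank-correlation test bed: returns a series sharing the target's uniform
#' grid, built as a weighted mix of the (standardized) index and white noise,
#' so its expected Spearman correlation with the index is controlled.
#'
#' @param t time grid (s).
#' @param x index values on that grid.
#' @param rho target correlation in [0, 1).
#' @param seed integer seed.
#' @return numeric vector of surrogate pressure values (arbitrary units).
#' @export
surrogatePressure <- function(t, x, rho = 0.7, seed = 0) {
  stopifnot(length(t) == length(x), rho >= 0, rho < 1)
  z <- (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  z[is.na(z)] <- 0
  eps <- .withSeed(seed, stats::rnorm(length(z)))
  rho * z + sqrt(1 - rho^2) * eps
}
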