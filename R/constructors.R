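# user-facing constructors; validity checks live on the classes

#' Construct an EcgSignal
#'
#' @param samples numeric amplitudes.
#' @param fs sampling frequency (Hz).
#' @param t0 time of the first sample (s).
#' @return an [EcgSignal-class].
#' @export
ecgSignal <- function(samples, fs, t0 = 0) {
  new("EcgSignal", samples = as.numeric(samples), fs = as.numeric(fs),
      t0 = as.numeric(t0))
}

#' Construct BeatAnnotations
#'
#' @param rTimes strictly increasing R-peak times (s).
#' @param labels optional per-beat labels.
#' @return a [BeatAnnotations-class].
#' @export
beatAnnotations <- function(rTimes, labels = character(0)) {
  new("BeatAnnotations", rTimes = as.numeric(rTimes),
      labels = as.character(labels))
}

#' Construct an IbiSeries
#'
#' @param t anchor times (s), one per interval, at the interval's closing beat.
#' @param ibi interval durations (s).
#' @return an [IbiSeries-class].
#' @export
ibiSeries <- function(t, ibi) {
  new("IbiSeries", t = as.numeric(t), ibi = as.numeric(ibi))
}

#' Construct a QtSeries
#'
#' @param t beat times (s).
#' @param qt QT durations (s).
#' @return a [QtSeries-class].
#' @export
qtSeries <- function(t, qt) {
  new("QtSeries", t = as.numeric(t), qt = as.numeric(qt))
}

#' Select a covariance estimation method
#'
#' @param name one of \code{"exact"}, \code{"robust"}, \code{"p95"},
#'   \code{"approximate"}.
#' @param outlierFraction assumed outlier fraction for the MCD-based
#'   \code{"p95"} variant; the standard variant keeps the default 0.05.
#' @param seed seed for the randomized MCD subset search (used only when the
#'   exhaustive search is infeasible).
#' @return a [CovMethod-class].
#' @export
covMethod <- function(name = c("robust", "exact", "p95", "approximate"),
                      outlierFraction = 0.05, seed = 0) {
  name <- match.arg(name)
  new("CovMethod", name = name, outlierFraction = outlierFraction,
      seed = seed)
}

#' Construct a UniformSeries
#'
#' @param values sample values.
#' @param fs sampling frequency (Hz).
#' @param t0 time of the first sample (s).
#' @return a [UniformSeries-class].
#' @export
uniformSeries <- function(values, fs = 4, t0 = 0) {
  new("UniformSeries", values = as.numeric(values), fs = as.numeric(fs),
      t0 = as.numeric(t0))
}

#' Configure a synthetic IPFM scenario
#'
#' Defaults describe a resting adult: 1.1 beats/s (66 bpm) baseline, a 0.1 Hz
#' LF and a 0.25 Hz HF rate modulation of 5% each, and 2 ms beat-timing
#' jitter. Step transitions are off unless \code{transitionTime} is set.
#'
#' @param duration record length (s).
#' @param baseRate baseline heart rate (beats/s).
#' @param aLf,fLf LF modulation amplitude (fraction of baseRate) and
#'   frequency (Hz).
#' @param aHf,fHf HF modulation amplitude and frequency (Hz).
#' @param transitionTime step-transition onset (s); NA disables it.
#' @param postRateFactor rate multiplier after the transition.
#' @param postAhfFactor HF-amplitude multiplier after the transition.
#' @param noiseSd sd of Gaussian beat-time jitter (s).
#' @param seed integer seed.
#' @return a [ScenarioConfig-class].
#' @export
scenarioConfig <- function(duration = 300, baseRate = 1.1,
                           aLf = 0.05, fLf = 0.1,
                           aHf = 0.05, fHf = 0.25,
                           transitionTime = NA_real_,
                           postRateFactor = 1, postAhfFactor = 1,
                           noiseSd = 0.002, seed = 0) {
  new("ScenarioConfig", duration = duration, baseRate = baseRate,
      aLf = aLf, fLf = fLf, aHf = aHf, fHf = fHf,
      transitionTime = as.numeric(transitionTime),
      postRateFactor = postRateFactor, postAhfFactor = postAhfFactor,
      noiseSd = noiseSd, seed = seed)
}

#' Cold-pressor scenario preset
#'
#' A 240 s record spanning -120 to +120 s around the stimulus onset: at the
#' transition the heart rate rises by 25% and the HF (respiratory sinus
#' arrhythmia) modulation drops to 40% of baseline, emulating the shift to
#' sympathetic dominance during hand immersion in ice water.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [scenarioConfig()].
#' @return a [ScenarioConfig-class] with \code{transitionTime = 120}
#'   (the record is generated on \code{[0, 240]}; analysis code treats 120 s
#'   as the onset).
#' @export
coldPressorScenario <- function(seed = 0, ...) {
  args <- list(duration = 240, baseRate = 1.1, aLf = 0.05, fLf = 0.1,
               aHf = 0.08, fHf = 0.25, transitionTime = 120,
               postRateFactor = 1.25, postAhfFactor = 0.4,
               noiseSd = 0.002, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(scenarioConfig, args)
}

#' Tilt-table scenario preset
#'
#' Same sign pattern as the cold pressor (rate up, HF modulation down) with a
#' milder rate change, emulating a passive head-up tilt.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [scenarioConfig()].
#' @return a [ScenarioConfig-class].
#' @export
tiltScenario <- function(seed = 0, ...) {
  args <- list(duration = 240, baseRate = 1.0, aLf = 0.05, fLf = 0.1,
               aHf = 0.08, fHf = 0.25, transitionTime = 120,
               postRateFactor = 1.15, postAhfFactor = 0.5,
               noiseSd = 0.002, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(scenarioConfig, args)
}

#' Specify an ectopic-beat (timing outlier) injection
#'
#' @param nOutliers number of beats to delay.
#' @param delay delay in seconds (default 0.030).
#' @param tLo,tHi placement window (s).
#' @param seed integer seed for the beat selection.
#' @return an [EctopicSpec-class].
#' @export
ectopicSpec <- function(nOutliers, delay = 0.030, tLo, tHi, seed = 0) {
  new("EctopicSpec", nOutliers = nOutliers, delay = delay,
      tLo = tLo, tHi = tHi, seed = seed)
}
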