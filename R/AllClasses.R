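#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Single-channel ECG signal
#'
#' Container for a uniformly sampled single-lead ECG trace. Amplitudes are in
#' millivolts (or the recording device's arbitrary units); time is always in
#' seconds.
#'
#' @slot samples numeric vector of sample amplitudes.
#' @slot fs sampling frequency in Hz (> 0).
#' @slot t0 time of the first sample in seconds.
#'
#' @seealso [readEcg()], [detectRPeaks()], [synthEcg()]
#' @export
setClass("EcgSignal",
  representation(samples = "numeric", fs = "numeric", t0 = "numeric"),
  prototype(t0 = 0)
)

setValidity("EcgSignal", function(object) {
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a single positive finite number")
  if (length(object@samples) == 0L)
    return("samples must be non-empty")
  if (!all(is.finite(object@samples)))
    return("samples must be finite (no NA/NaN/Inf)")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    return("t0 must be a single finite number")
  TRUE
})

#' R-peak beat annotations
#'
#' Strictly increasing R-peak occurrence times, in seconds, optionally with a
#' per-beat label (e.g. \code{"N"} for normal sinus beats).
#'
#' @slot rTimes strictly increasing beat times (s).
#' @slot labels character vector of per-beat labels; length 0 or
#'   \code{length(rTimes)}.
#'
#' @seealso [detectRPeaks()], [buildIbi()], [ipfmBeats()]
#' @export
setClass("BeatAnnotations",
  representation(rTimes = "numeric", labels = "character"),
  prototype(labels = character(0))
)

setValidity("BeatAnnotations", function(object) {
  if (length(object@rTimes) && !all(is.finite(object@rTimes)))
    return("rTimes must be finite")
  if (is.unsorted(object@rTimes, strictly = TRUE))
    return("rTimes must be strictly increasing")
  if (length(object@labels) &&
      length(object@labels) != length(object@rTimes))
    return("labels must be empty or match length(rTimes)")
  TRUE
})

#' Interbeat-interval series
#'
#' The central event series of the package: interval durations between
#' consecutive R-peaks. Each interval is anchored (timestamped) at its
#' closing beat, so \code{ibi[i] = t[i] - t[i-1]}-style reconstructions are
#' causal: the interval is known only once the second beat has occurred.
#'
#' @slot t anchor time of each interval, i.e. the time of its closing beat (s).
#' @slot ibi interval durations (s), all positive.
#'
#' @seealso [buildIbi()], [descriptorSeries()]
#' @export
setClass("IbiSeries", representation(t = "numeric", ibi = "numeric"))

setValidity("IbiSeries", function(object) {
  if (length(object@t) != length(object@ibi))
    return("t and ibi must have equal length")
  if (length(object@t) && is.unsorted(object@t, strictly = TRUE))
    return("t must be strictly increasing")
  if (length(object@ibi) && !all(object@ibi > 0))
    return("all ibi values must be positive")
  TRUE
})

#' QT-interval series
#'
#' Per-beat QT durations (Q-trough to T-end), in seconds, anchored at the
#' R-peak time of the beat they belong to.
#'
#' @slot t beat (R-peak) times (s).
#' @slot qt QT durations (s).
#'
#' @seealso [detectQt()], [lfQt()]
#' @export
setClass("QtSeries", representation(t = "numeric", qt = "numeric"))

setValidity("QtSeries", function(object) {
  if (length(object@t) != length(object@qt))
    return("t and qt must have equal length")
  if (length(object@t) && is.unsorted(object@t, strictly = TRUE))
    return("t must be strictly increasing")
  if (length(object@qt) && !all(object@qt > 0))
    return("all qt values must be positive")
  TRUE
})

#' Covariance estimation method
#'
#' Selects one of the four covariance back-ends used to extract SD1/SD2 from
#' the windowed Poincare cloud: \code{"exact"} (sample covariance, n-1
#' denominator), \code{"robust"} (Ledoit-Wolf shrinkage toward a scaled
#' identity), \code{"p95"} (fast minimum covariance determinant on the
#' h = round((1 - outlierFraction) n) subset with consistency rescaling) and
#' \code{"approximate"} (successive-difference closed forms, no covariance
#' matrix at all).
#'
#' @slot name one of \code{"exact"}, \code{"robust"}, \code{"p95"},
#'   \code{"approximate"}.
#' @slot outlierFraction assumed outlier fraction for \code{"p95"}; fixed at
#'   0.05 for the standard variant.
#' @slot seed integer seed controlling the subset search of \code{"p95"} when
#'   exhaustive enumeration is infeasible.
#'
#' @seealso [covMethod()], [estimateCovariance()]
#' @export
setClass("CovMethod",
  representation(name = "character", outlierFraction = "numeric",
                 seed = "numeric"),
  prototype(name = "robust", outlierFraction = 0.05, seed = 0)
)

setValidity("CovMethod", function(object) {
  ok <- c("exact", "robust", "p95", "approximate")
  if (length(object@name) != 1L || !(object@name %in% ok))
    return(sprintf("name must be one of %s", paste(ok, collapse = ", ")))
  f <- object@outlierFraction
  if (length(f) != 1L || !is.finite(f) || f < 0 || f >= 0.5)
    return("outlierFraction must lie in [0, 0.5)")
  TRUE
})

#' Time-resolved Poincare descriptor series
#'
#' CCD(t), SD1(t) and SD2(t) evaluated over a sliding causal window of length
#' \code{windowT}. Windows with fewer than the minimum number of lagged pairs
#' carry \code{NA}.
#'
#' @slot t evaluation times (s).
#' @slot ccd distance of the windowed Poincare centroid to the origin (s).
#' @slot sd1 dispersion perpendicular to the identity line (s).
#' @slot sd2 dispersion along the identity line (s).
#' @slot windowT window length (s).
#' @slot method the [CovMethod-class] used.
#'
#' @seealso [descriptorSeries()], [computeIndices()]
#' @export
setClass("DescriptorSeries",
  representation(t = "numeric", ccd = "numeric", sd1 = "numeric",
                 sd2 = "numeric", windowT = "numeric", method = "CovMethod")
)

setValidity("DescriptorSeries", function(object) {
  n <- length(object@t)
  if (length(object@ccd) != n || length(object@sd1) != n ||
      length(object@sd2) != n)
    return("t, ccd, sd1, sd2 must share one length")
  if (any(object@sd1 < 0, na.rm = TRUE) || any(object@sd2 < 0, na.rm = TRUE))
    return("sd1 and sd2 must be non-negative where defined")
  if (length(object@windowT) != 1L || object@windowT <= 0)
    return("windowT must be a single positive number")
  TRUE
})

#' Whole-recording Poincare anchors
#'
#' CCD0, SD01 and SD02 computed once from the full recording's lagged-pair
#' cloud; used to re-centre the demeaned time-resolved descriptors before
#' combining them into indices.
#'
#' @slot ccd0 whole-recording distance to the origin (s).
#' @slot sd01 whole-recording SD1 (s).
#' @slot sd02 whole-recording SD2 (s).
#' @slot method the [CovMethod-class] used.
#'
#' @seealso [globalAnchors()], [computeIndices()]
#' @export
setClass("GlobalAnchors",
  representation(ccd0 = "numeric", sd01 = "numeric", sd02 = "numeric",
                 method = "CovMethod")
)

#' Time-resolved autonomic index series
#'
#' CSI(t) and CPI(t): weighted combinations of the re-centred SD2/SD1
#' descriptor series with the (flipped) re-centred CCD trend. Units are
#' seconds-scaled arbitrary units; the weights and anchors used are recorded
#' with every output.
#'
#' @slot t evaluation times (s).
#' @slot csi cardiac sympathetic index.
#' @slot cpi cardiac parasympathetic index.
#' @slot ks weight of the slow-HRV (SD2) component in CSI.
#' @slot kp weight of the fast-HRV (SD1) component in CPI.
#' @slot anchors the [GlobalAnchors-class] used for re-centring.
#'
#' @seealso [computeIndices()]
#' @export
setClass("IndexSeries",
  representation(t = "numeric", csi = "numeric", cpi = "numeric",
                 ks = "numeric", kp = "numeric", anchors = "GlobalAnchors")
)

setValidity("IndexSeries", function(object) {
  n <- length(object@t)
  if (length(object@csi) != n || length(object@cpi) != n)
    return("t, csi, cpi must share one length")
  if (length(object@ks) != 1L || length(object@kp) != 1L)
    return("ks and kp must be single numbers")
  TRUE
})

#' Uniformly resampled series
#'
#' An event series (IBI or QT) interpolated onto a uniform grid, the input
#' expected by the quadratic time-frequency transform.
#'
#' @slot values sample values.
#' @slot fs sampling frequency (Hz), default 4.
#' @slot t0 time of the first sample (s).
#'
#' @seealso [resampleUniform()], [pseudoWignerVille()]
#' @export
setClass("UniformSeries",
  representation(values = "numeric", fs = "numeric", t0 = "numeric"),
  prototype(fs = 4, t0 = 0)
)

setValidity("UniformSeries", function(object) {
  if (length(object@fs) != 1L || object@fs <= 0)
    return("fs must be a single positive number")
  if (length(object@values) && !all(is.finite(object@values)))
    return("values must be finite")
  TRUE
})

#' Time-frequency power map
#'
#' Output of the smoothed pseudo Wigner-Ville transform: a non-negative power
#' surface on a time x frequency grid, plus the ambiguity-kernel parameters
#' and a burn-in mask flagging edge-contaminated times.
#'
#' @slot time time grid (s).
#' @slot freq frequency grid (Hz), covering [0, fs/2).
#' @slot power matrix, \code{length(time)} rows x \code{length(freq)}
#'   columns, clipped at zero.
#' @slot params list with kernel parameters \code{nu0}, \code{tau0},
#'   \code{lambda} and the sampling rate \code{fs}.
#' @slot burnin logical mask, TRUE where the time sample lies inside the
#'   edge burn-in region.
#'
#' @seealso [pseudoWignerVille()], [bandPower()]
#' @export
setClass("TfMap",
  representation(time = "numeric", freq = "numeric", power = "matrix",
                 params = "list", burnin = "logical")
)

setValidity("TfMap", function(object) {
  if (nrow(object@power) != length(object@time) ||
      ncol(object@power) != length(object@freq))
    return("power must be length(time) x length(freq)")
  if (any(!is.finite(object@power)))
    return("power must be finite")
  if (any(object@power < 0))
    return("power must be non-negative (clip before constructing)")
  TRUE
})

#' Time-resolved spectral band powers
#'
#' LF and HF band powers (and optionally LF from the QT series) on a shared
#' uniform time grid.
#'
#' @slot t time grid (s).
#' @slot lf low-frequency (0.04-0.15 Hz) power.
#' @slot hf high-frequency (0.15-0.4 Hz) power.
#' @slot lfqt LF power of the QT series, or NULL.
#'
#' @seealso [bandPower()], [lfQt()]
#' @export
setClass("SpectralBandSeries",
  representation(t = "numeric", lf = "numeric", hf = "numeric",
                 lfqt = "numericOrNULL"),
  prototype(lfqt = NULL)
)

#' Synthetic-scenario configuration
#'
#' Parameters of the IPFM (integral pulse frequency modulation) beat
#' generator: a baseline firing rate modulated by one LF and one HF sinusoid,
#' an optional step transition (rate scaled by \code{postRateFactor}, HF
#' modulation amplitude scaled by \code{postAhfFactor}) and Gaussian timing
#' jitter.
#'
#' @slot duration record length (s).
#' @slot baseRate baseline heart rate (beats/s).
#' @slot aLf,fLf LF modulation amplitude (fraction of baseRate) and
#'   frequency (Hz, within 0.04-0.15).
#' @slot aHf,fHf HF modulation amplitude and frequency (Hz, within
#'   0.15-0.4).
#' @slot transitionTime onset of the step transition (s), or NA for none.
#' @slot postRateFactor multiplicative rate change after the transition.
#' @slot postAhfFactor multiplicative HF-amplitude change after the
#'   transition.
#' @slot noiseSd standard deviation of additive beat-time jitter (s).
#' @slot seed integer seed for the jitter.
#'
#' @seealso [scenarioConfig()], [ipfmBeats()], [coldPressorScenario()]
#' @export
setClass("ScenarioConfig",
  representation(duration = "numeric", baseRate = "numeric",
                 aLf = "numeric", fLf = "numeric",
                 aHf = "numeric", fHf = "numeric",
                 transitionTime = "numeric", postRateFactor = "numeric",
                 postAhfFactor = "numeric", noiseSd = "numeric",
                 seed = "numeric")
)

setValidity("ScenarioConfig", function(object) {
  if (object@duration <= 0) return("duration must be positive")
  if (object@baseRate <= 0) return("baseRate must be positive")
  if (object@aLf < 0 || object@aHf < 0) return("amplitudes must be >= 0")
  if (object@aLf + object@aHf >= 1)
    return("aLf + aHf must be < 1 (rate must stay positive)")
  if (object@aLf > 0 && (object@fLf < 0.04 || object@fLf > 0.15))
    return("fLf must lie in [0.04, 0.15] Hz")
  if (object@aHf > 0 && (object@fHf <= 0.15 || object@fHf > 0.4))
    return("fHf must lie in (0.15, 0.4] Hz")
  if (object@postRateFactor <= 0) return("postRateFactor must be > 0")
  if (object@postAhfFactor < 0) return("postAhfFactor must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Ectopic-beat injection specification
#'
#' Describes a timing-outlier manipulation: \code{nOutliers} randomly chosen
#' R-peaks inside \code{[tLo, tHi]} are delayed by \code{delay} seconds, so
#' the interval closing at each shifted beat grows by \code{delay} and the
#' following interval shrinks by the same amount.
#'
#' @slot nOutliers number of beats to shift (0-10 in the standard
#'   robustness experiment).
#' @slot delay timing delay (s), default 0.030.
#' @slot tLo,tHi placement window bounds (s).
#' @slot seed integer seed for the beat selection.
#'
#' @seealso [ectopicSpec()], [injectEctopics()], [robustnessExperiment()]
#' @export
setClass("EctopicSpec",
  representation(nOutliers = "numeric", delay = "numeric",
                 tLo = "numeric", tHi = "numeric", seed = "numeric")
)

setValidity("EctopicSpec", function(object) {
  if (object@nOutliers < 0 || object@nOutliers != round(object@nOutliers))
    return("nOutliers must be a non-negative integer")
  if (object@delay <= 0) return("delay must be positive")
  if (object@tHi <= object@tLo) return("tHi must exceed tLo")
  TRUE
})
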