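# show(), accessors and coercions

#' @describeIn EcgSignal-class sample times
#' @param x object.
#' @export
setMethod("seriesTimes", "EcgSignal", function(x)
  x@t0 + (seq_along(x@samples) - 1) / x@fs)

#' @describeIn BeatAnnotations-class beat times
#' @param x object.
#' @export
setMethod("seriesTimes", "BeatAnnotations", function(x) x@rTimes)

#' @describeIn IbiSeries-class interval anchor times
#' @param x object.
#' @export
setMethod("seriesTimes", "IbiSeries", function(x) x@t)

#' @describeIn QtSeries-class beat times
#' @param x object.
#' @export
setMethod("seriesTimes", "QtSeries", function(x) x@t)

#' @describeIn DescriptorSeries-class evaluation times
#' @param x object.
#' @export
setMethod("seriesTimes", "DescriptorSeries", function(x) x@t)

#' @describeIn IndexSeries-class evaluation times
#' @param x object.
#' @export
setMethod("seriesTimes", "IndexSeries", function(x) x@t)

#' @describeIn UniformSeries-class sample times
#' @param x object.
#' @export
setMethod("seriesTimes", "UniformSeries", function(x)
  x@t0 + (seq_along(x@values) - 1) / x@fs)

#' @describeIn BeatAnnotations-class number of beats
#' @export
setMethod("nBeats", "BeatAnnotations", function(x) length(x@rTimes))

#' @describeIn IbiSeries-class number of intervals
#' @export
setMethod("nBeats", "IbiSeries", function(x) length(x@ibi))

#' Interval durations of an IbiSeries
#' @param x an [IbiSeries-class].
#' @return numeric vector of durations (s).
#' @export
ibiValues <- function(x) {
  stopifnot(is(x, "IbiSeries"))
  x@ibi
}

#' R-peak times of a BeatAnnotations object
#' @param x a [BeatAnnotations-class].
#' @return numeric vector of beat times (s).
#' @export
beatTimes <- function(x) {
  stopifnot(is(x, "BeatAnnotations"))
  x@rTimes
}

#' Sampling frequency
#' @param x an [EcgSignal-class] or [UniformSeries-class].
#' @return sampling frequency in Hz.
#' @export
samplingRate <- function(x) {
  stopifnot(is(x, "EcgSignal") || is(x, "UniformSeries"))
  x@fs
}

#' @describeIn IbiSeries-class two-column data.frame (t, ibi)
#' @export
setMethod("asTable", "IbiSeries", function(x)
  data.frame(t = x@t, ibi = x@ibi))

#' @describeIn QtSeries-class two-column data.frame (t, qt)
#' @export
setMethod("asTable", "QtSeries", function(x)
  data.frame(t = x@t, qt = x@qt))

#' @describeIn DescriptorSeries-class data.frame (t, ccd, sd1, sd2)
#' @export
setMethod("asTable", "DescriptorSeries", function(x)
  data.frame(t = x@t, ccd = x@ccd, sd1 = x@sd1, sd2 = x@sd2))

#' @describeIn IndexSeries-class data.frame (t, csi, cpi)
#' @export
setMethod("asTable", "IndexSeries", function(x)
  data.frame(t = x@t, csi = x@csi, cpi = x@cpi))

#' @describeIn SpectralBandSeries-class data.frame (t, lf, hf[, lfqt])
#' @export
setMethod("asTable", "SpectralBandSeries", function(x) {
  out <- data.frame(t = x@t, lf = x@lf, hf = x@hf)
  if (!is.null(x@lfqt)) out$lfqt <- x@lfqt
  out
})

#' @describeIn UniformSeries-class data.frame (t, value)
#' @export
setMethod("asTable", "UniformSeries", function(x)
  data.frame(t = seriesTimes(x), value = x@values))

setMethod("show", "EcgSignal", function(object) {
  cat(sprintf("EcgSignal: %d samples at %g Hz, %.1f s (t0 = %g s)\n",
              length(object@samples), object@fs,
              length(object@samples) / object@fs, object@t0))
})

setMethod("show", "BeatAnnotations", function(object) {
  n <- length(object@rTimes)
  cat(sprintf("BeatAnnotations: %d beats", n))
  if (n >= 2)
    cat(sprintf(" spanning %.1f s (mean rate %.2f beats/s)",
                diff(range(object@rTimes)),
                (n - 1) / diff(range(object@rTimes))))
  cat("\n")
})

setMethod("show", "IbiSeries", function(object) {
  n <- length(object@ibi)
  cat(sprintf("IbiSeries: %d intervals", n))
  if (n)
    cat(sprintf(", mean %.3f s (range %.3f-%.3f)",
                mean(object@ibi), min(object@ibi), max(object@ibi)))
  cat("\n")
})

setMethod("show", "QtSeries", function(object) {
  cat(sprintf("QtSeries: %d beats, mean QT %.3f s\n",
              length(object@qt),
              if (length(object@qt)) mean(object@qt) else NA))
})

setMethod("show", "CovMethod", function(object) {
  extra <- if (object@name == "p95")
    sprintf(" (outlierFraction = %.2f, seed = %d)", object@outlierFraction,
            as.integer(object@seed)) else ""
  cat(sprintf("CovMethod: %s%s\n", object@name, extra))
})

setMethod("show", "DescriptorSeries", function(object) {
  cat(sprintf(
    "DescriptorSeries: %d points, T = %g s, method = %s (%d missing)\n",
    length(object@t), object@windowT, object@method@name,
    sum(is.na(object@ccd))))
})

setMethod("show", "GlobalAnchors", function(object) {
  cat(sprintf(
    "GlobalAnchors (%s): CCD0 = %.4f s, SD01 = %.4f s, SD02 = %.4f s\n",
    object@method@name, object@ccd0, object@sd01, object@sd02))
})

setMethod("show", "IndexSeries", function(object) {
  cat(sprintf("IndexSeries: %d points, ks = %g, kp = %g\n",
              length(object@t), object@ks, object@kp))
})

setMethod("show", "UniformSeries", function(object) {
  cat(sprintf("UniformSeries: %d samples at %g Hz from t0 = %g s\n",
              length(object@values), object@fs, object@t0))
})

setMethod("show", "TfMap", function(object) {
  cat(sprintf(
    "TfMap: %d times x %d frequencies (0-%.3g Hz), kernel nu0 = %g, tau0 = %g, lambda = %g\n",
    length(object@time), length(object@freq), max(object@freq),
    object@params$nu0, object@params$tau0, object@params$lambda))
})

setMethod("show", "SpectralBandSeries", function(object) {
  cat(sprintf("SpectralBandSeries: %d points%s\n", length(object@t),
              if (is.null(object@lfqt)) "" else " (with LF_QT)"))
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(
    "ScenarioConfig: %g s at %g beats/s; LF %g@%g Hz, HF %g@%g Hz\n",
    object@duration, object@baseRate, object@aLf, object@fLf,
    object@aHf, object@fHf))
  if (is.finite(object@transitionTime))
    cat(sprintf("  transition at %g s: rate x%g, HF amplitude x%g\n",
                object@transitionTime, object@postRateFactor,
                object@postAhfFactor))
})

setMethod("show", "EctopicSpec", function(object) {
  cat(sprintf(
    "EctopicSpec: %d beats delayed by %+.0f ms in [%g, %g] s (seed %d)\n",
    as.integer(object@nOutliers), 1000 * object@delay, object@tLo,
    object@tHi, as.integer(object@seed)))
})
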