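# R-peak detection (Pan-Tompkins chain), IBI construction and quality
# flagging, and QT-interval extraction.

#' Detect R-peaks with a Pan-Tompkins chain
#'
#' The canonical chain: 5-15 Hz band-pass (zero-phase Butterworth), five-point
#' derivative, squaring, 150 ms moving-window integration, then adaptive
#' dual-threshold peak picking with a 200 ms refractory period and a
#' search-back pass for missed beats. Each accepted detection is refined to
#' the local extremum of the raw signal so reported times track the true
#' R-peak.
#'
#' @param ecg an [EcgSignal-class] with \code{fs >= 100} Hz and at least 5 s
#'   of data.
#' @param refractory minimum beat spacing (s), default 0.2.
#' @return a [BeatAnnotations-class] of strictly increasing R-peak times.
#' @export
detectRPeaks <- function(ecg, refractory = 0.2) {
  stopifnot(is(ecg, "EcgSignal"))
  fs <- ecg@fs
  if (fs < 100) stop("sampling rate must be at least 100 Hz")
  n <- length(ecg@samples)
  if (n / fs < 5) stop("signal must be at least 5 s long")
  x <- ecg@samples - mean(ecg@samples)
  if (stats::sd(x) == 0) stop("flat signal: no beats detectable")

  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bf, x))
  # five-point derivative (Pan-Tompkins weights), then squaring
  der <- stats::filter(xf, c(1, 2, 0, -2, -1) * fs / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  w <- max(2L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  mwi[is.na(mwi)] <- 0

  # candidate local maxima of the integrated signal
  up <- diff(mwi) > 0
  cand <- which(c(FALSE, up[-length(up)] & !up[-1], FALSE))
  if (!length(cand)) stop("no beats detected")

  refSamp <- round(refractory * fs)
  init <- seq_len(min(n, round(2 * fs)))
  spki <- max(mwi[init]) * 0.5
  npki <- mean(mwi[init]) * 0.5
  thr <- function() npki + 0.25 * (spki - npki)

  beats <- integer(0)
  lastQrs <- -Inf
  rrAvg <- NA_real_
  acceptedCand <- integer(0)
  for (ci in seq_along(cand)) {
    i <- cand[ci]
    v <- mwi[i]
    if (i - lastQrs < refSamp) {
      # within refractory: keep the larger of the two competing peaks
      if (length(beats) && v > mwi[beats[length(beats)]]) {
        beats[length(beats)] <- i
        acceptedCand[length(acceptedCand)] <- ci
        lastQrs <- i
        spki <- 0.125 * v + 0.875 * spki
      }
      next
    }
    if (v > thr()) {
      beats <- c(beats, i)
      acceptedCand <- c(acceptedCand, ci)
      spki <- 0.125 * v + 0.875 * spki
      if (length(beats) >= 2) {
        rrNew <- diff(utils::tail(beats, 9L))
        rrAvg <- mean(rrNew)
      }
      lastQrs <- i
    } else {
      npki <- 0.125 * v + 0.875 * npki
      # search-back: a long gap means a beat slipped under the threshold
      if (!is.na(rrAvg) && length(beats) &&
          (i - lastQrs) > 1.66 * rrAvg) {
        gap <- cand[cand > lastQrs + refSamp & cand < i]
        if (length(gap)) {
          j <- gap[which.max(mwi[gap])]
          if (mwi[j] > 0.5 * thr()) {
            beats <- c(beats, j)
            spki <- 0.25 * mwi[j] + 0.75 * spki
            lastQrs <- j
          }
        }
      }
    }
  }
  if (!length(beats)) stop("no beats detected")
  beats <- sort(unique(beats))

  # refine: integrated peaks lag the QRS by roughly the integration window;
  # take the raw-signal extremum in the trailing neighbourhood
  back <- as.integer(round((0.150 + 0.075) * fs))
  refined <- vapply(beats, function(i) {
    lo <- max(1L, as.integer(i) - back)
    seg <- x[lo:i]
    as.integer(lo + which.max(abs(seg)) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period on refined times (keep the larger peak)
  keep <- rep(TRUE, length(refined))
  lastIdx <- 1L
  for (k in seq_along(refined)[-1]) {
    if (refined[k] - refined[lastIdx] < refSamp) {
      if (abs(x[refined[k]]) > abs(x[refined[lastIdx]])) {
        keep[lastIdx] <- FALSE
        lastIdx <- k
      } else keep[k] <- FALSE
    } else lastIdx <- k
  }
  refined <- refined[keep]
  beatAnnotations(ecg@t0 + (refined - 1) / fs)
}

#' Build the interbeat-interval series from beat annotations
#'
#' \code{ibi[i] = rTimes[i+1] - rTimes[i]}, anchored at the closing beat
#' \code{rTimes[i+1]} so the series is causal.
#'
#' @param beats a [BeatAnnotations-class] with at least two beats.
#' @return an [IbiSeries-class] with \code{nBeats(beats) - 1} intervals.
#' @export
buildIbi <- function(beats) {
  stopifnot(is(beats, "BeatAnnotations"))
  r <- beats@rTimes
  if (length(r) < 2L) stop("at least two beats are required")
  ibiSeries(t = r[-1], ibi = diff(r))
}

#' Reconstruct beat times from an IBI series
#'
#' Inverse of [buildIbi()] under the closing-beat anchoring: the first beat
#' sits one interval before the first anchor, the remaining beats are the
#' anchors themselves.
#'
#' @param ibi an [IbiSeries-class].
#' @return a [BeatAnnotations-class].
#' @export
beatsFromIbi <- function(ibi) {
  stopifnot(is(ibi, "IbiSeries"))
  beatAnnotations(c(ibi@t[1] - ibi@ibi[1], ibi@t))
}

#' Flag candidate misdetections in an IBI series
#'
#' Large excursions of the IBI derivative mark suspect intervals: index
#' \code{i} is flagged when \code{|ibi[i] - ibi[i-1]|} exceeds
#' \code{thresholdFactor} times the median absolute deviation of all
#' successive differences. The series itself is never modified — flagging
#' surfaces candidates for review; use [dropFlagged()] to remove them
#' explicitly.
#'
#' @param ibi an [IbiSeries-class] with at least 3 intervals.
#' @param thresholdFactor positive multiple of the robust scale (default 4).
#' @return integer vector of flagged interval indices (possibly empty).
#' @export
flagMisdetections <- function(ibi, thresholdFactor = 4) {
  stopifnot(is(ibi, "IbiSeries"), thresholdFactor > 0)
  v <- ibi@ibi
  if (length(v) < 3L) stop("at least 3 intervals are required")
  d <- diff(v)
  scale <- stats::mad(d)
  if (scale < 1e-9) return(integer(0)) # degenerate: no usable spread
  which(abs(d) > thresholdFactor * scale) + 1L
}

#' Drop flagged intervals from an IBI series
#'
#' Convenience companion to [flagMisdetections()]; never applied implicitly.
#'
#' @param ibi an [IbiSeries-class].
#' @param flags integer indices to remove.
#' @return an [IbiSeries-class] without the flagged intervals.
#' @export
dropFlagged <- function(ibi, flags) {
  stopifnot(is(ibi, "IbiSeries"))
  if (!length(flags)) return(ibi)
  flags <- unique(as.integer(flags))
  stopifnot(all(flags >= 1L), all(flags <= length(ibi@ibi)))
  ibiSeries(ibi@t[-flags], ibi@ibi[-flags])
}

#' Extract the QT-interval series
#'
#' Per beat, the Q-trough is the signal minimum in the half-open window
#' \code{[R - 50 ms, R)} and the T-end the minimum in the closed window
#' \code{[R + 100 ms, R + 500 ms]}; \code{qt = t(T-end) - t(Q)}. Beats whose
#' search windows extend past the signal are dropped.
#'
#' @param ecg the [EcgSignal-class] the beats were detected on.
#' @param beats a [BeatAnnotations-class].
#' @return a [QtSeries-class] anchored at the R-peak times of retained beats.
#' @export
detectQt <- function(ecg, beats) {
  stopifnot(is(ecg, "EcgSignal"), is(beats, "BeatAnnotations"))
  fs <- ecg@fs
  if (fs < 100) stop("sampling rate must be at least 100 Hz")
  x <- ecg@samples
  n <- length(x)
  rIdx <- round((beats@rTimes - ecg@t0) * fs) + 1
  qLo <- rIdx - round(0.050 * fs)
  qHi <- rIdx - 1                      # [R - 50 ms, R): excludes R itself
  tLo <- rIdx + round(0.100 * fs)
  tHi <- rIdx + round(0.500 * fs)
  ok <- qLo >= 1 & tHi <= n & qHi >= qLo
  if (!any(ok)) stop("all beats have search windows outside the signal")
  tOut <- qtOut <- numeric(sum(ok))
  j <- 0L
  for (k in which(ok)) {
    j <- j + 1L
    qi <- qLo[k] + which.min(x[qLo[k]:qHi[k]]) - 1L
    ti <- tLo[k] + which.min(x[tLo[k]:tHi[k]]) - 1L
    tOut[j] <- beats@rTimes[k]
    qtOut[j] <- (ti - qi) / fs
  }
  qtSeries(tOut, qtOut)
}
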