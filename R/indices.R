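# Cardiac sympathetic / parasympathetic indices: re-centred combinations of
# the time-resolved Poincare descriptors.
#
#   D(t)   = (CCD(t) - mean CCD) + CCD0           re-centred cycle duration
#   Dflip  = 2 * mean(D) - D(t)                    D flipped about its mean
#   CPI(t) = kp * ((SD1(t) - mean SD1) + SD01) + D(t)
#   CSI(t) = ks * ((SD2(t) - mean SD2) + SD02) + Dflip(t)
#
# Means run over the analysed segment (trial scope); the anchors CCD0 / SD01 /
# SD02 come from the whole recording's Poincare cloud in one shot.

#' Whole-recording Poincare anchors
#'
#' Computes CCD0, SD01 and SD02 from the full recording's lagged-pair cloud,
#' with the same covariance method as the windowed series, to re-centre the
#' time-resolved descriptors.
#'
#' @param ibi an [IbiSeries-class] with at least 10 intervals.
#' @param method a [CovMethod-class].
#' @return a [GlobalAnchors-class].
#' @export
globalAnchors <- function(ibi, method = covMethod("robust")) {
  stopifnot(is(ibi, "IbiSeries"), is(method, "CovMethod"))
  v <- ibi@ibi
  n <- length(v)
  if (n < 10L) stop("at least 10 intervals are required")
  pairs <- new("LaggedPairs", x = v[-n], y = v[-1], refTime = ibi@t[n])
  ccd0 <- computeCcd(pairs)
  s <- if (method@name == "approximate") sdApproximate(v)
       else sdFromCovariance(estimateCovariance(pairs, method))
  new("GlobalAnchors", ccd0 = ccd0, sd01 = s[["sd1"]], sd02 = s[["sd2"]],
      method = method)
}

#' Combine descriptors into CSI and CPI
#'
#' Demeans each descriptor series over the analysed segment, re-centres it on
#' the whole-recording anchors, and combines: the parasympathetic index adds
#' the weighted SD1 deviation to the re-centred cycle-duration trend D(t);
#' the sympathetic index adds the weighted SD2 deviation to D(t) flipped
#' about its mean (shorter cycles, i.e. faster heart rate, push CSI up).
#'
#' Missing descriptor samples are linearly interpolated across gaps of at
#' most \code{maxGap} seconds before demeaning; longer gaps stay missing and
#' are excluded from the means.
#'
#' @param desc a [DescriptorSeries-class] with at least 2 non-missing entries.
#' @param anchors a [GlobalAnchors-class].
#' @param ks weight of the slow-HRV (SD2) component; default 1.
#' @param kp weight of the fast-HRV (SD1) component; default 10.
#' @param maxGap longest missing gap to interpolate (s).
#' @return an [IndexSeries-class].
#' @export
computeIndices <- function(desc, anchors, ks = 1, kp = 10, maxGap = 2) {
  stopifnot(is(desc, "DescriptorSeries"), is(anchors, "GlobalAnchors"))
  tt <- desc@t
  ccd <- .fillGaps(tt, desc@ccd, maxGap)
  sd1 <- .fillGaps(tt, desc@sd1, maxGap)
  sd2 <- .fillGaps(tt, desc@sd2, maxGap)
  if (sum(!is.na(ccd)) < 2L)
    stop("descriptor series has fewer than 2 usable entries")
  D <- (ccd - mean(ccd, na.rm = TRUE)) + anchors@ccd0
  Dflip <- 2 * mean(D, na.rm = TRUE) - D
  cpi <- kp * ((sd1 - mean(sd1, na.rm = TRUE)) + anchors@sd01) + D
  csi <- ks * ((sd2 - mean(sd2, na.rm = TRUE)) + anchors@sd02) + Dflip
  new("IndexSeries", t = tt, csi = csi, cpi = cpi, ks = ks, kp = kp,
      anchors = anchors)
}

#' Full pipeline from an IBI series to the index series
#'
#' Convenience wrapper chaining [descriptorSeries()], [globalAnchors()] and
#' [computeIndices()] with one window and method.
#'
#' @param ibi an [IbiSeries-class].
#' @param T window length (s), default 15.
#' @param method a [CovMethod-class], default robust.
#' @param ks,kp component weights, defaults 1 and 10.
#' @param ... further arguments for [descriptorSeries()].
#' @return an [IndexSeries-class].
#' @export
autonomicIndices <- function(ibi, T = 15, method = covMethod("robust"),
                             ks = 1, kp = 10, ...) {
  desc <- descriptorSeries(ibi, T = T, method = method, ...)
  computeIndices(desc, globalAnchors(ibi, method), ks = ks, kp = kp)
}

#' Coefficient sweep: condition separability over a (ks, kp) grid
#'
#' For every weight combination, computes per-trial mean CSI and CPI before
#' and after each trial's transition and runs the two-sided Wilcoxon
#' signed-rank test across trials. The descriptor series are computed once
#' per trial (they do not depend on the weights).
#'
#' @param trials list of trials, each a list with elements \code{ibi} (an
#'   [IbiSeries-class]) and \code{onset} (transition time, s); at least 6.
#' @param ksRange,kpRange weight grids (defaults 1:10).
#' @param T window length (s).
#' @param method a [CovMethod-class].
#' @return a list with \code{ks}, \code{kp}, matrices \code{zCsi} and
#'   \code{zCpi} (\code{length(ksRange)} x \code{length(kpRange)}), and
#'   \code{best}, the (ks, kp) pair maximizing |zCsi| + |zCpi|.
#' @export
sweepCoefficients <- function(trials, ksRange = 1:10, kpRange = 1:10,
                              T = 15, method = covMethod("robust")) {
  if (length(trials) < 6L) stop("at least 6 paired trials are required")
  parts <- lapply(trials, function(tr) {
    desc <- descriptorSeries(tr$ibi, T = T, method = method)
    anch <- globalAnchors(tr$ibi, method)
    tt <- desc@t
    ccd <- .fillGaps(tt, desc@ccd, 2)
    sd1 <- .fillGaps(tt, desc@sd1, 2)
    sd2 <- .fillGaps(tt, desc@sd2, 2)
    D <- (ccd - mean(ccd, na.rm = TRUE)) + anch@ccd0
    Dflip <- 2 * mean(D, na.rm = TRUE) - D
    s1 <- (sd1 - mean(sd1, na.rm = TRUE)) + anch@sd01
    s2 <- (sd2 - mean(sd2, na.rm = TRUE)) + anch@sd02
    pre <- tt <= tr$onset
    mpre <- function(v) mean(v[pre], na.rm = TRUE)
    mpost <- function(v) mean(v[!pre], na.rm = TRUE)
    list(D = c(mpre(D), mpost(D)), Df = c(mpre(Dflip), mpost(Dflip)),
         s1 = c(mpre(s1), mpost(s1)), s2 = c(mpre(s2), mpost(s2)))
  })
  zCsi <- matrix(NA_real_, length(ksRange), length(kpRange),
                 dimnames = list(ks = ksRange, kp = kpRange))
  zCpi <- zCsi
  for (a in seq_along(ksRange)) for (b in seq_along(kpRange)) {
    ks <- ksRange[a]; kp <- kpRange[b]
    csiPre <- vapply(parts, function(p) ks * p$s2[1] + p$Df[1], 0)
    csiPost <- vapply(parts, function(p) ks * p$s2[2] + p$Df[2], 0)
    cpiPre <- vapply(parts, function(p) kp * p$s1[1] + p$D[1], 0)
    cpiPost <- vapply(parts, function(p) kp * p$s1[2] + p$D[2], 0)
    zCsi[a, b] <- wilcoxonSignedRank(csiPre, csiPost)$z
    zCpi[a, b] <- wilcoxonSignedRank(cpiPre, cpiPost)$z
  }
  score <- abs(zCsi) + abs(zCpi)
  bi <- arrayInd(which.max(score), dim(score))
  list(ks = ksRange, kp = kpRange, zCsi = zCsi, zCpi = zCpi,
       best = c(ks = ksRange[bi[1]], kp = kpRange[bi[2]]))
}
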