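# Sliding-window Poincare geometry: CCD(t), SD1(t), SD2(t).
#
# The lag-1 Poincare plot pairs each interval with its successor. Over a
# causal window [t - T, t] we track (i) the centroid's distance to the origin
# (CCD) and (ii) the dispersion across / along the identity line (SD1 / SD2),
# read off the eigenstructure of the 2x2 covariance of the lagged pairs.

#' Lagged Poincare pairs
#'
#' Consecutive-interval pairs (IBI_i, IBI_{i+1}) drawn from one window.
#'
#' @slot x first-interval values (s).
#' @slot y successor-interval values (s).
#' @slot refTime reference (right-edge) time of the window (s).
#'
#' @seealso [windowPairs()]
#' @export
setClass("LaggedPairs",
  representation(x = "numeric", y = "numeric", refTime = "numeric")
)

setValidity("LaggedPairs", function(object) {
  if (length(object@x) != length(object@y))
    return("x and y must have equal length")
  TRUE
})

setMethod("show", "LaggedPairs", function(object) {
  cat(sprintf("LaggedPairs: %d pairs at t = %g s\n", length(object@x),
              object@refTime))
})

#' Extract the lagged pairs inside a causal window
#'
#' A pair (IBI_i, IBI_{i+1}) is included when the anchor times of both
#' intervals lie in \code{[t - T, t]} (closed on both sides). Because
#' intervals are anchored at their closing beat, the window is causal: no
#' information later than \code{t} enters.
#'
#' @param ibi an [IbiSeries-class].
#' @param t window right edge (s).
#' @param T window length (s), > 0.
#' @param centered if TRUE, use \code{[t - T/2, t + T/2]} instead (off by
#'   default; the standard analysis is causal).
#' @return a [LaggedPairs-class]; possibly empty.
#' @export
windowPairs <- function(ibi, t, T, centered = FALSE) {
  stopifnot(is(ibi, "IbiSeries"), T > 0)
  lo <- if (centered) t - T / 2 else t - T
  hi <- if (centered) t + T / 2 else t
  tt <- ibi@t
  n <- length(tt)
  if (n < 2)
    return(new("LaggedPairs", x = numeric(0), y = numeric(0), refTime = t))
  i <- seq_len(n - 1L)
  keep <- tt[i] >= lo & tt[i + 1L] <= hi
  new("LaggedPairs", x = ibi@ibi[i][keep], y = ibi@ibi[i + 1L][keep],
      refTime = t)
}

#' Distance of the Poincare centroid to the origin
#'
#' \code{sqrt(mean(x)^2 + mean(y)^2)}: the baseline cardiac cycle duration
#' descriptor for the window.
#'
#' @param pairs a [LaggedPairs-class].
#' @return CCD in seconds, or NA for an empty window.
#' @export
computeCcd <- function(pairs) {
  stopifnot(is(pairs, "LaggedPairs"))
  if (length(pairs@x) == 0L) return(NA_real_)
  sqrt(mean(pairs@x)^2 + mean(pairs@y)^2)
}

# Ledoit-Wolf analytic shrinkage toward the scaled identity mu*I,
# mu = trace(S)/p; intensity from the analytic optimum, clipped to [0, 1].
.ledoitWolf <- function(X) {
  n <- nrow(X)
  p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2) / p
  if (d2 <= .Machine$double.eps)
    return(diag(mu, p) * n / max(n - 1, 1))
  # E||x_k x_k' - S||_F^2 summed: sum (x_k'x_k)^2 - n ||S||_F^2
  q <- rowSums(Xc^2)
  b2bar <- (sum(q^2) - n * sum(S^2)) / (n^2 * p)
  b2 <- min(b2bar, d2)
  rho <- max(0, min(1, b2 / d2))
  Sig <- rho * diag(mu, p) + (1 - rho) * S
  # report on the sample (n-1) scale used everywhere else
  Sig * n / max(n - 1, 1)
}

# chi-square consistency factor so the MCD scatter is unbiased under
# Gaussian data when a fraction (1 - alpha) is trimmed
.mcdConsistency <- function(alpha, p = 2) {
  if (alpha >= 1) return(1)
  alpha / stats::pchisq(stats::qchisq(alpha, df = p), df = p + 2)
}

# Minimum covariance determinant for bivariate clouds.
# Exhaustive over all h-subsets when the number of dropped points is small
# (the usual case for 15 s windows); otherwise FastMCD-style concentration
# (C-) steps from random (p+1)-point starts, seeded for reproducibility.
.fastMCD <- function(X, h, seed = 0, nstart = 100L, maxCsteps = 20L) {
  n <- nrow(X)
  p <- ncol(X)
  if (h >= n) {
    Sig <- stats::cov(X)
    return(list(cov = Sig, center = colMeans(X), support = seq_len(n)))
  }
  stopifnot(h > p)
  subsetCov <- function(idx) {
    xs <- X[idx, , drop = FALSE]
    list(center = colMeans(xs), cov = stats::cov(xs))
  }
  detOf <- function(S) S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  # squared Mahalanobis distances via the analytic 2x2 inverse; NULL when the
  # scatter is numerically singular
  mahal2 <- function(S, center) {
    dt <- detOf(S)
    if (!is.finite(dt) || dt <= 1e-14 * max(S[1, 1] + S[2, 2], 1e-300)^2)
      return(NULL)
    dx <- X[, 1] - center[1]
    dy <- X[, 2] - center[2]
    (S[2, 2] * dx^2 - 2 * S[1, 2] * dx * dy + S[1, 1] * dy^2) / dt
  }
  best <- NULL
  bestDet <- Inf
  drop <- n - h
  if (drop >= 1 && choose(n, drop) <= 5000) {
    combos <- utils::combn(n, drop)
    for (j in seq_len(ncol(combos))) {
      idx <- setdiff(seq_len(n), combos[, j])
      fit <- subsetCov(idx)
      dt <- detOf(fit$cov)
      if (is.finite(dt) && dt < bestDet) {
        bestDet <- dt
        best <- c(fit, list(support = idx))
      }
    }
  } else {
    .withSeed(seed, {
      for (s in seq_len(nstart)) {
        idx0 <- sample.int(n, p + 1L)
        fit <- subsetCov(idx0)
        if (!is.finite(detOf(fit$cov)) || detOf(fit$cov) <= 0) {
          # grow a degenerate start until the scatter is non-singular
          k <- p + 1L
          while (detOf(fit$cov) <= 0 && k < n) {
            k <- k + 1L
            idx0 <- sample.int(n, k)
            fit <- subsetCov(idx0)
          }
          if (detOf(fit$cov) <= 0) next
        }
        idx <- idx0
        prevDet <- Inf
        for (it in seq_len(maxCsteps)) {
          d2 <- mahal2(fit$cov, fit$center)
          if (is.null(d2)) break
          idx <- order(d2)[seq_len(h)]
          fit <- subsetCov(idx)
          dt <- detOf(fit$cov)
          if (!is.finite(dt) || dt <= 0 || dt >= prevDet * (1 - 1e-12)) break
          prevDet <- dt
        }
        if (length(idx) != h) next # start never reached a full h-subset
        dt <- detOf(fit$cov)
        if (is.finite(dt) && dt > 0 && dt < bestDet) {
          bestDet <- dt
          best <- c(fit, list(support = idx))
        }
      }
    })
  }
  if (is.null(best)) { # fully degenerate cloud: fall back to the plain cov
    return(list(cov = stats::cov(X), center = colMeans(X),
                support = seq_len(n)))
  }
  best
}

#' Covariance of a windowed Poincare cloud
#'
#' Dispatches on the [CovMethod-class]: \describe{
#'   \item{exact}{sample covariance (n-1 denominator).}
#'   \item{robust}{Ledoit-Wolf analytic shrinkage toward the scaled identity
#'     \code{mu*I}, \code{mu = trace(S)/2}, intensity clipped to [0, 1].}
#'   \item{p95}{minimum covariance determinant over the
#'     \code{h = round((1 - outlierFraction) * n)} subset with the smallest
#'     determinant, rescaled by the chi-square consistency factor so it is
#'     unbiased under Gaussian data. The subset search is exhaustive when
#'     feasible and seeded FastMCD concentration otherwise.}
#' }
#' The \code{"approximate"} method has no covariance matrix; use
#' [sdApproximate()] instead.
#'
#' @param pairs a [LaggedPairs-class].
#' @param method a [CovMethod-class].
#' @return a symmetric positive-semidefinite 2x2 matrix (s^2), or a 2x2 NA
#'   matrix when the window holds too few pairs.
#' @export
estimateCovariance <- function(pairs, method = covMethod("exact")) {
  stopifnot(is(pairs, "LaggedPairs"), is(method, "CovMethod"))
  X <- cbind(pairs@x, pairs@y)
  n <- nrow(X)
  naCov <- matrix(NA_real_, 2, 2)
  if (method@name == "approximate")
    stop("the approximate method bypasses the covariance matrix; ",
         "use sdApproximate()")
  if (n < 3L) return(naCov)
  if (method@name == "exact") return(stats::cov(X))
  if (method@name == "robust") return(.ledoitWolf(X))
  # p95
  h <- round((1 - method@outlierFraction) * n)
  h <- max(h, 4L)
  if (h > n) h <- n
  fit <- .fastMCD(X, h = h, seed = method@seed)
  fit$cov * .mcdConsistency(h / n, p = 2)
}

#' SD1/SD2 from a Poincare covariance matrix
#'
#' Eigen-decomposes the 2x2 covariance and assigns the square roots of the
#' eigenvalues by eigenvector orientation: the eigenvector closer to the
#' identity-line direction (1,1) carries SD2 (long-term variability), the one
#' closer to (1,-1) carries SD1 (short-term variability). When the
#' orientation is ambiguous (axis-aligned eigenvectors, i.e. zero lag-1
#' covariance), the larger eigenvalue goes to SD2.
#'
#' @param covMat symmetric PSD 2x2 matrix (s^2).
#' @return named numeric vector \code{c(sd1 = , sd2 = )} in seconds.
#'   Eigenvalues below \code{-1e-12 * trace} raise an error; tiny negatives
#'   are clamped to zero.
#' @export
sdFromCovariance <- function(covMat) {
  if (any(is.na(covMat))) return(c(sd1 = NA_real_, sd2 = NA_real_))
  stopifnot(is.matrix(covMat), all(dim(covMat) == 2))
  if (abs(covMat[1, 2] - covMat[2, 1]) >
      1e-8 * (abs(covMat[1, 2]) + abs(covMat[2, 1]) + 1e-300))
    stop("covariance matrix must be symmetric")
  e <- eigen((covMat + t(covMat)) / 2, symmetric = TRUE)
  scale <- sum(diag(covMat))
  if (any(e$values < -1e-12 * max(scale, 1)))
    stop("covariance matrix has a materially negative eigenvalue")
  vals <- pmax(e$values, 0)
  align <- abs(colSums(e$vectors * c(1, 1)) / sqrt(2)) # |v . (1,1)|/sqrt(2)
  if (abs(align[1] - align[2]) < 1e-9) {
    sd2i <- which.max(vals)
  } else {
    sd2i <- which.max(align)
  }
  sd1i <- 3L - sd2i
  c(sd1 = sqrt(vals[sd1i]), sd2 = sqrt(vals[sd2i]))
}

#' Successive-difference (approximate) SD1/SD2
#'
#' Closed forms that avoid the covariance matrix entirely:
#' \code{SD1 = sqrt(1/2) * sd(diff(ibi))} and
#' \code{SD2 = sqrt(|2 * sd(ibi)^2 - 1/2 * sd(diff(ibi))^2|)}, both with the
#' sample (n-1) convention.
#'
#' @param ibiWindow numeric vector of interval durations inside one window (s).
#' @return named vector \code{c(sd1 = , sd2 = )}, NA when fewer than 3
#'   intervals are available.
#' @export
sdApproximate <- function(ibiWindow) {
  w <- as.numeric(ibiWindow)
  if (length(w) < 3L) return(c(sd1 = NA_real_, sd2 = NA_real_))
  sdd <- stats::sd(diff(w))
  sdw <- stats::sd(w)
  c(sd1 = sqrt(0.5) * sdd,
    sd2 = sqrt(abs(2 * sdw^2 - 0.5 * sdd^2)))
}

#' Time-resolved Poincare descriptors over a sliding window
#'
#' Evaluates CCD, SD1 and SD2 at every interval anchor time (per-beat grid)
#' or on a uniform grid, over the trailing window \code{[t - T, t]}. Windows
#' holding fewer than \code{minPairs} lagged pairs yield NA.
#'
#' @param ibi an [IbiSeries-class].
#' @param T window length in seconds; default 15 s, the reporting
#'   configuration.
#' @param method a [CovMethod-class]; default robust (Ledoit-Wolf).
#' @param grid \code{"per-beat"} or \code{"uniform"}.
#' @param dt grid step for \code{grid = "uniform"} (s).
#' @param minPairs minimum lagged pairs per window (default 3).
#' @param centered evaluate on centred windows \code{[t - T/2, t + T/2]}
#'   instead of causal ones (off by default).
#' @return a [DescriptorSeries-class].
#' @export
descriptorSeries <- function(ibi, T = 15, method = covMethod("robust"),
                             grid = c("per-beat", "uniform"), dt = 0.25,
                             minPairs = 3L, centered = FALSE) {
  stopifnot(is(ibi, "IbiSeries"), is(method, "CovMethod"))
  grid <- match.arg(grid)
  tt <- ibi@t
  if (length(tt) < 2L || diff(range(tt)) <= T)
    stop("recording duration must exceed the window length T")
  evalT <- if (grid == "per-beat") tt else seq(tt[1], tt[length(tt)], by = dt)
  m <- length(evalT)
  ccd <- sd1 <- sd2 <- rep(NA_real_, m)
  approx <- method@name == "approximate"
  v <- ibi@ibi
  # anchors are sorted, so each window is a contiguous index range
  wLo <- if (centered) evalT - T / 2 else evalT - T
  wHi <- if (centered) evalT + T / 2 else evalT
  lo <- findInterval(wLo, tt, left.open = TRUE) + 1L # first anchor >= wLo
  hi <- findInterval(wHi, tt)                        # last anchor <= wHi
  for (k in seq_len(m)) {
    nPairs <- hi[k] - lo[k]
    if (nPairs < minPairs) next
    i <- lo[k]:(hi[k] - 1L)
    x <- v[i]
    y <- v[i + 1L]
    ccd[k] <- sqrt(mean(x)^2 + mean(y)^2)
    if (approx) {
      s <- sdApproximate(v[lo[k]:hi[k]])
    } else {
      X <- cbind(x, y)
      cv <- switch(method@name,
        exact = stats::cov(X),
        robust = .ledoitWolf(X),
        p95 = {
          h <- min(max(round((1 - method@outlierFraction) * nPairs), 4L),
                   nPairs)
          .fastMCD(X, h = h, seed = method@seed)$cov *
            .mcdConsistency(h / nPairs, p = 2)
        })
      s <- sdFromCovariance(cv)
    }
    sd1[k] <- s[["sd1"]]
    sd2[k] <- s[["sd2"]]
  }
  new("DescriptorSeries", t = evalT, ccd = ccd, sd1 = sd1, sd2 = sd2,
      windowT = T, method = method)
}
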