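# Statistical procedures and experiment harnesses: condition separability,
# window-length analysis, ectopic-beat robustness, index-pressure correlation.

#' z-score a series per trial
#'
#' Centers and scales to unit sample variance (n-1 convention) over the
#' non-missing samples. Constant input is an error, never silent zeros.
#'
#' @param x numeric vector (NAs allowed and preserved).
#' @return numeric vector with mean 0 and sd 1 over non-missing entries.
#' @export
zscorePerTrial <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) < 2L) stop("at least 2 non-missing samples are required")
  s <- stats::sd(v)
  if (s == 0) stop("zero variance: cannot z-score a constant series")
  (x - mean(v)) / s
}

#' Two-sided Wilcoxon signed-rank test for paired trials
#'
#' Zero differences are discarded (classic convention). W is the sum of the
#' ranks (midranks under ties) of the positive differences; Z uses the normal
#' approximation with tie correction. For n <= 12 retained pairs the p-value
#' is computed exactly by enumerating all 2^n sign assignments; otherwise
#' from the normal approximation.
#'
#' @param pre,post equal-length per-trial values; at least 5 non-zero
#'   differences must remain.
#' @param nComparisons Bonferroni divisor; the returned \code{alpha} is
#'   \code{0.05 / nComparisons}.
#' @return an object of class \code{"pairedComparison"}: a list with
#'   \code{statistic} (W), \code{z}, \code{p}, \code{n}, \code{alpha},
#'   \code{exact} and the per-trial means.
#' @export
wilcoxonSignedRank <- function(pre, post, nComparisons = 1) {
  stopifnot(length(pre) == length(post))
  keep <- !is.na(pre) & !is.na(post)
  d <- post[keep] - pre[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero")
  if (n < 5) stop("fewer than 5 non-zero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
  z <- (W - mu) / sqrt(sig2)
  exact <- n <= 12
  if (exact) {
    # enumerate the signed-rank distribution over all 2^n sign patterns
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = W, z = z, p = p, n = n,
                 alpha = 0.05 / nComparisons, exact = exact,
                 meanPre = mean(pre[keep]), meanPost = mean(post[keep])),
            class = "pairedComparison")
}

#' @export
print.pairedComparison <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank: W = %g, Z = %.3f, p = %.4g (%s, n = %d)\n",
    x$statistic, x$z, x$p, if (x$exact) "exact" else "normal approx.", x$n))
  cat(sprintf("  mean pre = %.4f, mean post = %.4f, alpha = %.4g\n",
              x$meanPre, x$meanPost, x$alpha))
  invisible(x)
}

#' Friedman test for paired samples across conditions
#'
#' Rank-based chi-square statistic with tie correction (midranks), identical
#' in form to the classic direct rank formula; p-value from the chi-square
#' distribution with k - 1 degrees of freedom.
#'
#' @param mat numeric matrix, trials in rows (>= 5) and conditions in columns
#'   (>= 3).
#' @return list with \code{statistic}, \code{df} and \code{p}.
#' @export
friedmanStat <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  k <- ncol(mat)
  if (k < 3) stop("at least 3 conditions are required")
  if (n < 5) stop("at least 5 trials are required")
  r <- t(apply(mat, 1L, rank))
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  ties <- apply(mat, 1L, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  })
  den <- n * k * (k + 1) - sum(ties) / (k - 1)
  stat <- if (num == 0) 0 else num / den
  list(statistic = stat, df = k - 1,
       p = stats::pchisq(stat, df = k - 1, lower.tail = FALSE))
}

#' Spearman correlation with the t-distribution approximation
#'
#' rho is the Pearson correlation of midranks;
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} with a two-sided p. The
#' significance flag additionally requires a positive rho — an
#' anti-correlated pair is never called significant however small its p.
#'
#' @param x,y equal-length series (>= 10 points after masking).
#' @param alpha significance level (default 1e-4).
#' @param exclude optional logical mask of samples to drop (e.g. an initial
#'   orthostatic-hypotension interval).
#' @return list with \code{rho}, \code{t}, \code{p}, \code{n} and
#'   \code{significant}.
#' @export
spearmanT <- function(x, y, alpha = 1e-4, exclude = NULL) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(exclude)) keep <- keep & !exclude
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 10) stop("at least 10 paired samples are required")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero rank variance")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    tval <- sign(rho) * Inf
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, t = tval, p = p, n = n,
       significant = (p < alpha) && (rho > 0))
}

#' Binomial post hoc test on the proportion of significant cases
#'
#' Upper-tail probability \code{P(X >= nSignificant)} for
#' \code{X ~ Binomial(nTotal, pNull)} — does a majority-like share of
#' participants show the effect?
#'
#' @param nSignificant number of significant cases.
#' @param nTotal number of cases.
#' @param pNull null proportion (default 0.5).
#' @return the upper-tail p-value.
#' @export
binomialPosthoc <- function(nSignificant, nTotal, pNull = 0.5) {
  stopifnot(nSignificant >= 0, nSignificant <= nTotal)
  if (pNull <= 0 || pNull >= 1) stop("pNull must lie in (0, 1)")
  stats::pbinom(nSignificant - 1, nTotal, pNull, lower.tail = FALSE)
}

#' Effect magnitude of a condition transition
#'
#' Mean of the series over \code{(onset, onset + span]} minus its mean over
#' \code{[onset - span, onset]}.
#'
#' @param index an [IndexSeries-class], or a numeric vector with times in
#'   \code{t}.
#' @param onset transition time (s).
#' @param span averaging span on each side (s), default 120.
#' @param which \code{"csi"} or \code{"cpi"} when \code{index} is an
#'   [IndexSeries-class].
#' @param t times (s) when \code{index} is a plain vector.
#' @return the effect magnitude (same units as the series).
#' @export
effectMagnitude <- function(index, onset, span = 120,
                            which = c("csi", "cpi"), t = NULL) {
  which <- match.arg(which)
  if (is(index, "IndexSeries")) {
    t <- index@t
    v <- if (which == "csi") index@csi else index@cpi
  } else {
    v <- as.numeric(index)
    if (is.null(t)) stop("t must be given for a plain numeric series")
  }
  pre <- t >= onset - span & t <= onset
  post <- t > onset & t <= onset + span
  if (sum(pre & !is.na(v)) == 0 || sum(post & !is.na(v)) == 0)
    stop("series does not cover both sides of [onset - span, onset + span]")
  mean(v[post], na.rm = TRUE) - mean(v[pre], na.rm = TRUE)
}

#' Ectopic-beat robustness experiment
#'
#' Quantifies each covariance method's sensitivity to timing outliers: for
#' every outlier count n and repetition, n beats are delayed by
#' \code{delay} seconds, the full CSI pipeline is re-run, and the effect
#' magnitude across \code{onset} is measured. By default the CSI series is
#' z-scored per run first, matching the per-trial normalization used in the
#' group statistics, so noisier estimators show deflated effects.
#'
#' @param ibi a clean [IbiSeries-class] with a genuine pre/post effect.
#' @param onset transition time (s).
#' @param methods list of [CovMethod-class] objects (default: all four).
#' @param nRange outlier counts (default 0:10).
#' @param reps repetitions (random outlier placements) per count.
#' @param seed base seed; run (n, r) uses \code{seed + 1000 n + r}.
#' @param T window length (s).
#' @param ks,kp index weights.
#' @param span effect-magnitude span (s).
#' @param placement length-2 vector: the outlier placement window (default
#'   \code{onset + c(-span, span)}).
#' @param zscore z-score the CSI series before measuring the effect
#'   (default TRUE).
#' @return named list, one entry per method: a list with \code{n} (the
#'   counts), \code{effect} (reps x counts matrix), \code{medByN},
#'   \code{madByN}, and scalars \code{median} and \code{mad} summarizing all
#'   runs (the Fig-7C-style summary).
#' @export
robustnessExperiment <- function(ibi, onset,
                                 methods = list(covMethod("exact"),
                                                covMethod("robust"),
                                                covMethod("p95"),
                                                covMethod("approximate")),
                                 nRange = 0:10, reps = 20, seed = 0,
                                 T = 15, ks = 1, kp = 10, span = 120,
                                 placement = NULL, zscore = TRUE) {
  stopifnot(is(ibi, "IbiSeries"))
  if (is.null(placement)) placement <- onset + c(-span, span)
  beats0 <- beatsFromIbi(ibi)
  out <- list()
  for (m in methods) {
    eff <- matrix(NA_real_, reps, length(nRange),
                  dimnames = list(NULL, nRange))
    for (jn in seq_along(nRange)) {
      nOut <- nRange[jn]
      for (r in seq_len(reps)) {
        if (nOut == 0 && r > 1) {
          eff[r, jn] <- eff[1, jn] # no randomness without outliers
          next
        }
        b <- if (nOut == 0) beats0 else
          injectEctopics(beats0, ectopicSpec(
            nOutliers = nOut, tLo = placement[1], tHi = placement[2],
            seed = seed + 1000 * nOut + r))
        ib <- buildIbi(b)
        idx <- autonomicIndices(ib, T = T, method = m, ks = ks, kp = kp)
        csi <- if (zscore) zscorePerTrial(idx@csi) else idx@csi
        eff[r, jn] <- effectMagnitude(csi, onset = onset, span = span,
                                      t = idx@t)
      }
    }
    medByN <- apply(eff, 2, stats::median)
    madByN <- apply(eff, 2, stats::mad)
    out[[m@name]] <- list(n = nRange, effect = eff,
                          medByN = medByN, madByN = madByN,
                          median = stats::median(eff),
                          mad = stats::mad(eff))
  }
  out
}
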