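---
title: "Time-resolved cardiac autonomic indices from Poincare plot geometry"
author: "poincareHRV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved cardiac autonomic indices from Poincare plot geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poincareHRV)
```

## The model

Heartbeats are paced by the sinoatrial node under continuous sympathetic and
parasympathetic modulation. Sympathetic activation shortens the cardiac cycle
and predominantly drives slow (low-frequency, 0.04-0.15 Hz) heart-rate
variability; parasympathetic (vagal) activity lengthens the cycle and drives
the fast, mostly respiratory (0.15-0.4 Hz) beat-to-beat variability. The
classic spectral LF/HF surrogates separate these influences by frequency
alone, which is known to be fragile in the LF range where both branches
contribute.

This package instead tracks the geometry of the lag-1 Poincare plot — the
scatter of each interbeat interval (IBI) against its successor — inside a
sliding causal window `[t - T, t]`:

* `CCD(t) = sqrt(mean(x)^2 + mean(y)^2)`, the distance of the window's
  centroid to the origin, a baseline cardiac-cycle-duration descriptor
  (`x` and `y` are the first and second members of the lagged pairs);
* `SD1(t)` and `SD2(t)`, the square roots of the eigenvalues of the 2x2
  covariance of the pairs, assigned by eigenvector orientation: the
  eigenvector nearer the identity line `(1, 1)` carries SD2 (long-term
  variability), the one nearer `(1, -1)` carries SD1 (short-term,
  vagally-dominated variability).

Each descriptor series is demeaned over the analysed segment and re-centred
on whole-recording anchors `CCD0`, `SD01`, `SD02`, giving
`D(t) = (CCD(t) - mean CCD) + CCD0` and its flip about the mean,
`Dflip(t) = 2 mean(D) - D(t)`. The indices are

```
CPI(t) = kp * ((SD1(t) - mean SD1) + SD01) + D(t)
CSI(t) = ks * ((SD2(t) - mean SD2) + SD02) + Dflip(t)
```

so CSI rises when cycles shorten (sympathetic-like) and with weighted slow
HRV, while CPI rises with long cycles and weighted fast HRV. With
`ks = kp = 0` the indices collapse to pure heart-rate trends (`CSI = Dflip`,
`CPI = D`) and the index deviation from the trend is exactly linear in the
weights — two identities the test suite checks.

## Parameters that matter

* **Window length `T` (s), default 15.** Shorter windows track fast changes
  but under-sample the 0.04-0.15 Hz band (a 5 s window sees at most half an
  LF cycle); longer windows smooth vagal dynamics away. `descriptorSeries()`
  evaluates on the per-beat grid by default; a uniform grid is available.
  `sweepCoefficients()` and `friedmanStat()` support re-deriving the
  window-length and weight choices on any cohort.
* **Weights `ks = 1`, `kp = 10` (dimensionless), the reporting defaults.**
  `ks = 1` keeps the sympathetic index dominated by the heart-rate
  component; `kp = 10` lets fast HRV dominate the parasympathetic index.
* **Covariance method, default `"robust"`.** Four back-ends:
  `exact` (sample covariance, n-1), `robust` (Ledoit-Wolf analytic shrinkage
  toward the scaled identity `mu*I`, `mu = trace/2`, intensity clipped to
  [0, 1]), `p95` (minimum covariance determinant over
  `h = round(0.95 n)` points, chi-square consistency-rescaled; exhaustive
  subset search when `choose(n, n-h) <= 5000`, seeded FastMCD concentration
  otherwise), and `approximate` (successive-difference closed forms
  `SD1 = sqrt(1/2) sd(diff(ibi))`,
  `SD2 = sqrt(|2 sd(ibi)^2 - 1/2 sd(diff(ibi))^2|)`). The exact and
  approximate routes are algebraically equivalent up to finite-window edge
  terms; the suite checks 5% median agreement on stationary series.
* **`minPairs = 3`.** Windows with fewer lagged pairs yield missing values;
  `computeIndices()` linearly interpolates missing gaps up to 2 s and
  excludes longer gaps from the means.

## Numerical choices

* Time is seconds everywhere inside the package; milliseconds are accepted
  only at I/O boundaries (`readBeats(units = "ms")`).
* Intervals are anchored at their closing beat, so the trailing window is
  strictly causal. A centred window exists behind `centered = TRUE`, off by
  default.
* Sample statistics use the n-1 denominator throughout, including the
  successive-difference forms.
* Eigenvalues are assigned to SD1/SD2 by eigenvector orientation, not by
  magnitude, so a window dominated by alternating (negatively lag-correlated)
  rhythm correctly reports SD1 > SD2. Ties (axis-aligned eigenvectors, i.e.
  zero lag-covariance) put the larger eigenvalue on SD2. Eigenvalues below
  -1e-12 x trace are an error; small negatives are clamped to zero.
* The MCD subset search is deterministic: exhaustive enumeration for the
  window sizes a 15 s window produces (drop of 1-2 points), seeded FastMCD
  with 100 concentration starts otherwise. The chi-square consistency factor
  `alpha / P(chisq_4 <= q_alpha)` makes it unbiased under Gaussian data.

## The spectral comparator

The LF/HF comparator resamples the event series to 4 Hz with cubic splines,
takes the Wigner-Ville distribution of the analytic signal, and filters it in
the ambiguity domain with the elliptical kernel
`exp{-pi [(nu/nu0)^2 + (tau/tau0)^2]^(2 lambda)}` before integrating the LF
(0.04-0.15 Hz) and HF (0.15-0.4 Hz) bands; the same machinery applied to the
QT-interval series gives LF_QT. Negative time-frequency values are clipped at
zero and the first/last `1/(2 x 0.04) = 12.5` s are flagged as burn-in.

The kernel is the one deliberate approximation site. The literature quotes
`nu0 = 0.03`, `tau0 = 0.06`, `lambda = 0.3` without fixing the axis units; we
adopt the classic time-frequency-toolbox normalization (doppler in cycles per
sample, lag as a fraction of the record length), under which those values
reproduce the quoted ~10 s time and ~0.04 Hz frequency resolutions for 4 Hz
records of a few hundred seconds. With `tau0` read as seconds instead, the
kernel suppresses every nonzero lag at 4 Hz sampling and the map degenerates
to a flat spectrum, so that reading is untenable. All kernel parameters are
exposed; every validation of the comparator is a qualitative band-dominance
or symmetry property robust to the convention.

## What the synthetic generator emulates — and what it does not

`ipfmBeats()` implements integral pulse frequency modulation: beats fire when
the integral of `baseRate (1 + aLf sin(2 pi fLf t) + aHf sin(2 pi fHf t))`
crosses integers, with optional step transitions (rate x `postRateFactor`,
HF amplitude x `postAhfFactor`) and Gaussian beat-timing jitter. The
`coldPressorScenario()` preset fixes the study conditions used throughout the
tests: 240 s records analysed from -120 to +120 s around the onset, baseline
1.1 beats/s, LF modulation 0.05 at 0.1 Hz, HF modulation 0.08 at 0.25 Hz,
and at the onset a 25% rate increase with the HF amplitude dropping to 40% —
the canonical shift toward sympathetic dominance. `tiltScenario()` is the
milder variant. 2 ms timing jitter models trigger noise at a 200-500 Hz
acquisition. Cohorts perturb rate and amplitudes log-normally between
subjects (10% default).

The generator controls spectral content exactly, which is what the
comparator and sign-recovery tests need. It does **not** emulate heavy-tailed
physiological HRV, respiratory non-stationarity, true ectopy (it models
timing displacement, +30 ms, not inserted/deleted beats), or baroreflex
feedback. Consequently the windowed Poincare clouds are ring-like rather
than Gaussian-with-outliers. One documented consequence: the
trimming-based `p95` estimator, which on real recordings degrades the effect
estimate visibly (trimming removes genuine variability), is nearly inert on
these clouds — dropping one of ~15 ring points barely changes the scatter —
so the expectation that `p95` shows the smallest clean-data effect magnitude
is not reproduced by this generator, and the corresponding check in the
validation suite documents that honestly rather than adjusting the
conditions. Passing tests here demonstrate algebraic and statistical
correctness of the machinery, not field performance on clinical ECG.

## Statistical harness

`wilcoxonSignedRank()` (exact enumeration for n <= 12, tie-corrected normal
approximation otherwise, zeros discarded), `friedmanStat()` (midrank formula
with tie correction), `spearmanT()` (t-approximation, significance requires
positive rho), and `binomialPosthoc()` (upper-tail cumulative binomial,
configurable null proportion, default 0.5) replicate the validation logic:
per-trial z-scoring, paired pre/post comparison at Bonferroni-corrected
alpha (0.05/4 for the sympathetic markers, 0.05/3 for the parasympathetic
ones), window-length analysis across 5/10/15/20/25 s, correlation against a
concurrent pressure series at alpha = 1e-4, and the ectopic-beat robustness
experiment (`robustnessExperiment()`, 0-10 injected +30 ms delays, effect
magnitude on the per-run z-scored CSI — the z-scoring scale matches the
per-trial normalization used by the group statistics).

Problem sizes used by the validation suite and the acceptance script —
240-460 s records, 10-50 replicate series, 20-subject cohorts, 10-20
robustness repetitions, 5000 calibration simulations — were chosen as the
smallest sizes at which the sampling error of each checked quantity is well
inside its tolerance.

## Worked example

```{r example, eval = FALSE}
beats <- ipfmBeats(coldPressorScenario(seed = 1))
ecg <- synthEcg(beats, fs = 200, snrDb = 15, seed = 1)
det <- detectRPeaks(ecg)
ibi <- buildIbi(det)
flagMisdetections(ibi) # candidate misdetections: flag-only, never dropped

idx <- autonomicIndices(ibi, T = 15, method = covMethod("robust"))
effectMagnitude(idx, onset = 120, span = 120)                 # CSI: > 0
effectMagnitude(idx, onset = 120, span = 120, which = "cpi")  # CPI: < 0

bands <- spectralBands(ibi, qt = detectQt(ecg, det))
```

## Known limitations

* No manual/interactive beat correction: misdetections are flagged, never
  auto-repaired; `dropFlagged()` must be called explicitly.
* Indices are in seconds-scaled arbitrary units; no mapping to absolute
  neural activity is attempted.
* Lag-1 Poincare geometry only; no lag-m plots or nonlinear descriptors.
* The WFDB support covers single-signal format-16 records and beat
  annotations — enough to exchange data with the standard tools, not a full
  reader. Sample amplitudes round-trip only to ADC quantization.
* On short windows the MCD consistency factor assumes Gaussian data; for
  strongly oscillatory windows it mildly over-corrects (see the generator
  section above).
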