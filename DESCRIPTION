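Package: poincareHRV
Title: Time-Resolved Cardiac Autonomic Indices from Poincare Plot Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Time-resolved estimation of cardiac sympathetic (CSI) and
    parasympathetic (CPI) indices from ECG-derived interbeat intervals.
    Tracks the geometry of the lag-1 Poincare plot (distance to the origin
    and the SD1/SD2 ellipse dispersions) over a sliding window, with exact,
    Ledoit-Wolf shrinkage, minimum-covariance-determinant and
    successive-difference covariance back-ends. Includes a Pan-Tompkins
    R-peak detector, QT-interval extraction, a smoothed pseudo Wigner-Ville
    LF/HF spectral comparator, an integral pulse frequency modulation (IPFM)
    synthetic data generator with cold-pressor and tilt scenarios, and the
    non-parametric statistical harness (Wilcoxon, Friedman, Spearman,
    binomial post hoc, ectopic-beat robustness experiments) used to
    validate the indices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, signal
Suggests: testthat (>= 3.0.0), MASS, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
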