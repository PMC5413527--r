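Package: spectsync
Title: Phase Dyssynchrony Analysis for Gated Myocardial Perfusion SPECT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for left-ventricular mechanical dyssynchrony analysis from
    ECG-gated myocardial perfusion SPECT. Extracts regional time-activity
    curves from gated short-axis count volumes, fits first- and second-order
    Fourier harmonics to obtain contraction phase and time to end-systole,
    and computes the standard dyssynchrony indices: phase standard deviation,
    95% histogram bandwidth, normalized phase entropy, and the segmental
    TES family (MDTES, SDTES, DTES-LS) on the AHA 17-segment model. Includes
    a digital gated-SPECT phantom in which wall thickening drives apparent
    counts through the partial-volume effect, a threshold-based cavity
    volume and ejection-fraction estimator, and cohort-level statistics
    (normal limits, sex comparisons, correlation and regression with
    ventricular volume and ejection fraction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
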