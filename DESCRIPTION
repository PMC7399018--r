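Package: nirsrep
Title: Test-Retest Reproducibility Analysis for Functional Near-Infrared
    Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying within-subject
    test-retest reproducibility of functional near-infrared spectroscopy
    (fNIRS) activation maps. Covers conversion of dual-wavelength light
    intensities to optical density, motion-artifact correction by spline
    interpolation and wavelet thresholding, hemoglobin concentration
    estimation through the modified Beer-Lambert law, short-separation
    channel regression within an AR-prewhitened robust general linear
    model, dual-chromophore activation classification, and the size (Rq)
    and overlap (Ro) reproducibility indices with their physiological
    variability regression. Includes a synthetic-study generator that
    emulates a block-designed finger-tapping experiment with systemic
    physiology, motion artifacts, and session-to-session probe
    displacement, plus SVD-based rigid landmark registration for
    neuronavigated probe placement.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
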