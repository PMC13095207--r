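Package: alphaSDT
Title: Alpha-Band Phase Effects on Perceptual Sensitivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how the phase of
    pre-stimulus alpha-band (7-14 Hz) EEG oscillations modulates perceptual
    sensitivity in yes/no detection tasks. Provides a synthetic-data module
    (double-pass session designs, band-limited noise stimuli with embedded
    Gabor targets, phase-dependent signal-detection observers, dipole-like
    alpha EEG), a phase-estimation chain (individual alpha frequency
    detection, post-stimulus tapering, FIR band-pass filtering, analytic
    signal phase, phase binning, alpha-power channel selection),
    phase-binned signal detection statistics (d-prime and criterion with
    loglinear correction) with permutation and cluster-based inference,
    circular statistics (V-test, resultant vectors, phase opposition),
    double-pass response-consistency analysis, and reverse-correlation
    classification images with 2-D Gaussian tuning fits and bootstrap
    modulation tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'synth-design.R'
    'synth-stimuli.R'
    'synth-eeg.R'
    'synth-observer.R'
    'phaseprep.R'
    'sdt.R'
    'circular.R'
    'coupling.R'
    'doublepass.R'
    'revcorr-bank.R'
    'revcorr-ci.R'
    'revcorr-fit.R'
    'pipeline.R'
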