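Package: collafib
Title: Radiation-Response Analysis of Type I Collagen Fibrils
Version: 0.1.0
Authors@R: person("Collafib", "Maintainers", email = "maintainers@collafib.org", role = c("aut", "cre"))
Description: Tools for quantifying the effects of ionizing radiation on type I
    collagen fibrils from four instrument channels: automated morphometry of
    atomic force microscopy (AFM) height images (patching into 1 micron
    regions of interest, spatial-spectral texture features, per-metric linear
    discriminant classifiers with leave-one-out consistency and a
    threshold-based change rule), Hertzian pyramid indentation-modulus
    extraction from force-distance curves, tri-exponential fluorescence
    lifetime fitting of time-correlated single photon counting histograms
    with amplitude-weighted average lifetimes, attenuated total reflectance
    Fourier-transform infrared (ATR-FTIR) amide-band metrics with a
    denaturation signature, and photon dosimetry arithmetic. A seeded
    synthetic-data module generates fibril image phantoms with ground-truth
    labels, force curves, decay histograms and collagen-like spectra so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
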