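Package: fretscreen
Title: FRET-Based Screening Analysis for Respiratory Chain Supercomplex Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for sensitized-emission FRET screens of
    mitochondrial respiratory chain supercomplex formation. Estimates
    spectral bleed-through and cross-excitation coefficients from
    single-fluorophore calibration cells, computes corrected FRET
    (cFRET) and cFRET/donor ratios per region of interest, aggregates
    wells, scores compound plates against vehicle and positive controls
    with replicate-consistency and viability exclusion filters, fits
    four-parameter logistic dose-response curves for EC50 estimation,
    computes Z'-factor assay quality, and derives Mito Stress Test
    respirometry metrics and qPCR fold changes. Includes a synthetic-data
    generator with known ground truth that emulates the screen's
    statistical structure, plus an image-level path (segmentation, ROI
    measurement, pixelwise FRET-ratio maps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
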