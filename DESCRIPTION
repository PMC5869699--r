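Package: sapphireT1
Title: Systolic Saturation-Recovery Cardiac T1 Mapping Simulation and Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and estimation toolkit for systolic
    saturation-pulse prepared heart-rate independent inversion-recovery
    (SAPPHIRE) T1 mapping. Generates numerical short-axis cardiac and vial
    phantoms as complex base-image series under realistic ECG triggering,
    including RR-interval variability and mis-triggering; reconstructs T1
    maps with a three-parameter nonlinear least-squares fit using either
    magnitude polarity restoration or phase-sensitive polarity mapping; and
    evaluates maps with accuracy/precision statistics, coefficients of
    variation, septal line-profile full-width-at-half-maximum, extracellular
    volume fractions, and angular sector segmentation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    RNifti,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
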