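Package: serumEEM
Title: Serum Retinol Calibration from Excitation-Emission Matrix Fluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for predicting serum retinol concentration
    from excitation-emission matrix (EEM) fluorescence of untreated serum.
    Provides an EEM data model with CSV input/output, Rayleigh/Raman scatter
    excision and interpolation, trilinear PARAFAC decomposition by
    nonnegativity-constrained alternating least squares with missing-data
    handling and the core-consistency diagnostic, NIPALS PLS1 calibration
    with cross-validated latent-variable selection, RMSEE/RMSEP/RPD metrics,
    variable-importance-in-projection (VIP) and coefficient contour maps,
    Y-permutation validation, and a synthetic serum-EEM generator with known
    trilinear ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
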