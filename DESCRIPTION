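Package: rbekit
Title: Empirical Proton RBE Modelling from Photon Radiosensitivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling the relative biological effectiveness (RBE)
    of therapeutic proton beams from linear-quadratic photon survival-curve
    parameters and the beam's dose-weighted linear energy transfer (LET).
    Implements linear-quadratic survival-curve mathematics with delta-method
    uncertainty propagation, ingestion and quality filtering of paired
    photon/proton clonogenic-survival tables, a six-parameter empirical model
    that maps photon iso-survival doses to proton iso-survival doses through
    LET-dependent slope and intercept laws, BIC-based selection among
    candidate LET functions and survival-endpoint combinations, retrainable
    Wedenberg, McNamara and Mairani-style comparison models, leave-one-out
    cross-validation with bootstrap prediction intervals, a synthetic paired
    survival-data generator, and voxel-wise application of any fitted model
    to co-registered dose and LET grids to produce RBE-weighted dose maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
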