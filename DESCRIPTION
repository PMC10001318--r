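Package: bnctsf
Title: Cell-Level Survival-Fraction Modelling of BNCT and X-ray
    Radiotherapy for Infiltrating Glioblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates cell-by-cell treatment response of diffusely
    infiltrating glioblastoma on a two-dimensional cellular lattice.
    Builds microscopic-extension-probability (MEP) infiltration fields
    (circular, elliptical, irregular), maps them to boron-10
    biodistributions, generates surrogate multi-component dose matrices
    for boron neutron capture therapy (alpha, lithium-7, gamma,
    residual neutron) and fractionated X-ray fields with a hypoxic-core
    oxygen enhancement ratio, weights components by relative biological
    effectiveness, calibrates to a single-fraction prescription, and
    evaluates heterogeneous linear-quadratic survival. Reports regional
    and differential (radial-shell) survival fractions with
    run-ensemble uncertainties and the survival-fraction change from
    extending the clinical target volume margin.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
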