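Package: RVGeometry
Title: Retinal Vascular Bifurcation Geometry and Retinopathy Grade Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Measures retinal vascular bifurcation geometry (parent and
    child vessel widths, branching angles, Murray-law junction exponents
    and derived ratios) from fundus-style images with centreline
    annotations, and analyses the resulting feature tables: group
    comparisons across diabetic retinopathy grades with one-way ANOVA and
    Fisher-protected LSD post-hoc tests, multiple linear regression of
    geometry on demographic and clinical risk factors, binary logistic
    regression for retinopathy progression, intra-observer repeatability
    as coefficients of variation, and leave-one-out cross-validated
    logistic models for patient-level grade assessment with optic nerve
    head distance-ratio matching. Includes a synthetic-data module that
    renders bifurcation images with exact ground truth and simulates
    hierarchical patient cohorts, so the whole pipeline is testable
    without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
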