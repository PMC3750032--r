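Package: falut
Title: Nonlinear Normative Color Look-Up Tables for Brain Fractional Anisotropy Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds nonlinear color look-up tables (LUTs) for fractional
    anisotropy (FA) maps from normative region-of-interest measurements.
    Population means and 95% prediction intervals per ROI group are estimated
    with a random-intercept linear mixed model, placed as color inflection
    points, and connected by continuous per-channel ramps. Includes synthetic
    normative-cohort and FA-phantom generators, application of the LUT to
    NIfTI FA volumes with slice-mosaic rendering, ImageJ/CSV LUT export, and
    validation statistics (Bland-Altman agreement between acquisition schemes,
    sensitivity/specificity of screening reads).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    RNifti,
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
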