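Package: actdose
Title: Delivered-Dose Evaluation for Lung SABR via Adaptive-CT Deformable Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end evaluation of the dose actually delivered to lung
    stereotactic ablative radiotherapy (SABR) targets, on synthetic phantom
    cohorts. Generates planning-CT-like phantoms with ITV/PTV structures,
    simulates per-fraction setup errors and smooth anatomic deformations,
    builds adaptive CTs by rigid plus multipass B-spline deformable
    registration, propagates target structures, computes per-fraction doses
    from an analytic plan model, warps them back to the planning frame and
    averages them. Extracts dose-volume histogram statistics, plan-quality
    indices (HI, CI, GI, GM), and registration QA metrics (Dice, surface
    distances, displacement and log-Jacobian statistics), and analyses the
    drivers of PTV D95% with stepwise multiple linear regression
    (tolerance/VIF collinearity diagnostics) and one-way ANOVA by lung lobe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
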