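Package: serumexposome
Title: Serum Exposome Biomonitoring and Chronic-Disease Risk Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch-specific internal-standard-calibrated quantification of
    multi-class chemical panels from targeted mass-spectrometry peak tables,
    with quality-control evaluation (limits of quantification, precision,
    recovery, batch-effect diagnostics), chronic-disease outcome
    classification with propensity-score matched controls, single-exposure
    logistic and linear risk models, weighted quantile sum regression and
    quantile g-computation for mixture effects, and guidance-value hazard
    quotients with spline dose-risk curves. Includes a synthetic-study
    generator that emulates a large biomonitoring cohort (calibration
    ladders, interleaved QC spikes, multiplicative per-batch instrument
    drift shared with matched internal standards) so the whole pipeline is
    exercisable and testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
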