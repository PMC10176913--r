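Package: flexpoly
Title: Flexible Polynomial Trajectories for Sparsely Measured Clinical Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates personalised, daily-resolution trajectories of sparsely
    measured continuous clinical outcomes (such as FEV1 percent predicted or
    BMI) by per-subject flexible polynomial regression: ordinary least-squares
    polynomials of order 1 to 4 are fitted to each individual's repeated
    measurements and the order with the lowest AIC is selected, subject to
    sparsity-conditional rules (a forced linear model below 8 measurements,
    and segmentation at gaps of 6 months or more below 15 measurements).
    Selected models are evaluated on an integer daily grid between the first
    and last measurement with pointwise confidence bands and implausibility
    flags, so that infrequent clinical outcomes can be aligned with densely
    captured remote-monitoring exposures. Includes eligibility screening,
    model-selection stability under 80 percent subsampling, pairwise
    observed-versus-predicted change evaluation, and a synthetic-cohort
    generator with known polynomial ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
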