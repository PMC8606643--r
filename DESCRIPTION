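Package: embma
Title: Model-Based Meta-Analysis of Aggregate Trial Time Courses with an
    Emax Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a time-course Emax model to placebo-adjusted change rates
    extracted from aggregate (arm-level) randomized controlled trial reports,
    the model-based meta-analysis (MBMA) setting. Provides maximum-likelihood
    estimation with inter-study random effects (Laplace approximation) and
    sample-size-weighted residuals, objective-function-value covariate
    selection, study-level bootstrap uncertainty, conditional weighted
    residual diagnostics, prediction-corrected visual predictive checks,
    Monte-Carlo efficacy prediction, and a synthetic aggregate-trial
    generator with stored ground truth for end-to-end validation. Ships an
    aggregate-data fixture of published carnitine trials in type 2 diabetes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
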