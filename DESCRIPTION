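Package: fewlevels
Title: Monte Carlo Assessment of Mixed Models with Few Grouping-Factor Levels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation machinery to assess whether fixed-effect estimates
    from linear mixed-effects models (random intercept, fitted by restricted
    maximum likelihood) degrade when the grouping factor has fewer than five
    levels, compared with ordinary linear models that code the grouping
    factor as fixed effects. Provides an unbalanced grouped Gaussian data
    generator with full seed control, a profiled-REML random-intercept
    fitter with singular-fit detection, Monte Carlo evaluation metrics
    (coverage probability, relative RMSE, bias, variance-component recovery,
    singular-fit proportions, stratification by singularity), an experiment
    orchestrator for the 3x3 grid of sample sizes and group counts, and
    command-line entry points with CSV/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    parallel,
    tools,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
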