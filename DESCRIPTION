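Package: tbcea
Title: Trial-Based Cost-Effectiveness Analysis for Psychotherapy Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial-based economic evaluation of psychotherapy for
    depression, built around a twice-weekly versus once-weekly session
    frequency comparison. Constructs quality-adjusted life-years from EQ-5D-5L
    utilities by the area-under-the-curve method, values resource use,
    informal care and lost productivity (friction-cost or human-capital
    approach) from a societal or healthcare perspective, handles missing
    outcome and cost data by multiple imputation with chained equations and
    predictive mean matching pooled by Rubin's rules, quantifies uncertainty
    by bias-corrected and accelerated bootstrapping, and summarises results as
    incremental cost-effectiveness ratios, cost-effectiveness planes and
    acceptability curves. A seeded synthetic trial generator emulating a 2x2
    factorial randomised controlled trial makes the whole pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
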