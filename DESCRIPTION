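Package: vkr
Title: Virtual Knee Replacement Case-Control Analysis of Cartilage Thickness Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying femorotibial cartilage thickness loss in knees
    that reach a "virtual knee replacement" (vKR) symptom state defined purely
    from patient-reported outcomes (KOOS pain and quality-of-life scores).
    Provides a deterministic synthetic generator for OAI-like longitudinal
    knee cohorts, the published decision rule that classifies knee-years as
    vKR cases, specificity-based threshold calibration, an auditable
    exclusion cascade, stratified 1:1 case-control matching with an age
    caliper, aggregation of subregion cartilage thickness into compartment
    variables and location-independent thinning/thickening scores, and the
    matched-pair statistical toolkit (paired t-tests, 1:1 conditional
    logistic regression with odds ratios per control standard deviation and a
    cluster-robust sandwich covariance, BMI-category adjustment, and
    Kruskal-Wallis sensitivity comparisons), composed into a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
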