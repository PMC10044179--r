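Package: paialloc
Title: Personalised Advantage Index Pipelines for Differential Psychotherapy Allocation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating data-driven differential treatment allocation
    between two psychotherapies (cognitive-behavioural therapy versus counselling
    for depression) from routinely collected patient records. Provides a synthetic
    electronic-healthcare-record cohort generator with confounded treatment
    assignment and known treatment-by-covariate interactions; cohort selection
    filters with attrition logging; balanced train/test partitioning checked by
    standardised mean differences; iterative random-forest imputation for
    mixed-type baseline data with NRMSE/PFC error reporting; doubly robust
    propensity-adjusted linear outcome models with treatment interactions and
    likelihood-ratio moderator tests; Personalised Advantage Index (PAI) scoring
    with counterfactual predictions and optimal/suboptimal allocation groups; and
    clinically-thresholded outcome evaluation (recovery, reliable change,
    reliable recovery, percent and absolute minimal clinically important
    difference) compared by odds ratios and mean differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
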