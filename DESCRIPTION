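Package: prevcomplete
Title: Complete Cancer Prevalence from Limited-Duration Registry Data via
    Completeness Indexes
Version: 0.1.0
Authors@R: person("Registry", "Methods", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates complete cancer prevalence from limited-duration
    population-based cancer registry observations using completeness
    (R-) indexes. Implements the counting method for limited-duration
    prevalence with life-table weighting of patients lost to follow-up,
    Ederer II cohort relative survival, Weibull mixture cure models,
    logistic age-cohort incidence models with nonparametric 10-year
    birth-cohort effects, model-based and empirical R-index construction,
    and the APRD/PRD validation statistics. Ships a registry
    microsimulator with a brute-force complete-prevalence oracle so the
    whole pipeline can be validated against known generative truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse,
    tools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
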