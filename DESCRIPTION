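Package: adncprev
Title: Population Prevalence of Alzheimer's Disease Neuropathological
    Change from Plasma pTau217
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the population prevalence of Alzheimer's disease
    neuropathological change (ADNC) from plasma pTau217 in selectively
    observed cohorts. Implements two-cutoff biomarker classification with an
    intermediate zone, multi-stage inverse-probability-of-selection
    weighting with median +/- 3 IQR trimming, weighted stratified prevalence
    estimation with Wilson intervals on the Kish effective sample size,
    AD-continuum staging, Bayes positive/negative predictive value grid
    sensitivity analysis with optimism shrinkage, CKD-EPI 2021 eGFR and
    segmented (piecewise) regression of log pTau217 on kidney function,
    and treatment-eligibility estimation with chained-equation multiple
    imputation. Ships a synthetic cohort generator that reproduces the
    selection structure such analyses must correct for, so every estimator
    is testable against known generative truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    nnet,
    glmnet
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
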