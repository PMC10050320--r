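Package: riskamb
Title: Risk and Ambiguity Valuation Modeling with Simulated Choice and ROI
    fMRI Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying subjective valuation of uncertain monetary
    gains and losses and its neural encoding. Implements a behavioral
    economics choice model (power utility with linear ambiguity discounting
    and softmax choice), per-subject maximum-likelihood estimation of risk
    and ambiguity attitudes, a deterministic 240-trial lottery task design,
    a synthetic-cohort generator with clinical symptom profiles and
    region-of-interest BOLD-like time series under value or saliency coding,
    first-level GLMs with parametric subjective-value modulators, and
    group-level inference including symptom correlations, covariate-adjusted
    effects, value/saliency group tests with FDR correction, exhaustive
    best-subset regression by BIC, and PCA of clinical measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lhs,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
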