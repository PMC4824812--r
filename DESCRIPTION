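Package: ommurine
Title: Oral Minimal Model Indices and Post-Load Urinary Glucose and
    C-Peptide for Extended OGTT Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates beta-cell responsivity (Phi basal/static/dynamic/oral),
    insulin sensitivity (S_I) and disposition indices from extended 3.5-hour
    oral glucose tolerance test (OGTT) curves with the oral minimal model,
    using two-compartment C-peptide kinetics with van Cauter population rate
    constants.  Relates model-based renal C-peptide flux (the k01 flux AUC)
    and renal glucose clearance to pooled post-load urine collections,
    estimates the renal glucose threshold by stepwise grid exclusion, and
    computes urine-plasma Spearman correlation tables and family-adjusted ROC
    c-indices.  Ships a synthetic OGTT cohort generator with WHO subgroup and
    family structure so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    lme4,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
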