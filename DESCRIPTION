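Package: grsurv
Title: Genetic Risk Scores and Left-Truncated Survival for Screening Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes an odds-ratio-weighted, population-standardized polygenic
    genetic risk score (GRS) for prostate cancer, stratifies men into risk
    groups by GRS and family history, and analyses age at diagnosis in
    screening cohorts with delayed entry: left-truncated Kaplan-Meier curves,
    log-rank and trend log-rank tests, and Cox proportional hazards regression
    with staggered entry. Includes contingency-table association statistics
    (Pearson chi-square, Cochran-Armitage trend, one-way ANOVA), readers for
    SNP panel tables, dosage matrices and minimal VCF, and a simulator of
    biopsy-monitored chemoprevention-trial cohorts with known truth for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
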