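Package: bmibias
Title: Quantile-Matching Correction of Self-Report Bias in Survey BMI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects self-reported body mass index (BMI) in population surveys
    against a reference survey with measured anthropometry by quantile matching:
    quantile-specific differences between the self-reported and measured BMI
    distributions are estimated by sex and age group, smoothed with cubic
    splines, and applied to each participant at their sample-weighted BMI
    quantile. Includes a synthetic paired-survey generator with known ground
    truth, sequential cohort exclusion filters with an auditable log, a
    weighted two-sample Kolmogorov-Smirnov check, design-weighted prevalence
    estimation of severe obesity (BMI >= 40) with logit-transformed confidence
    intervals, and reporting utilities for published-style state and subgroup
    prevalence tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
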