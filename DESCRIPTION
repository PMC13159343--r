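Package: marginscan
Title: Resection-Margin Threshold Scanning for Local-Recurrence Risk in
    Myxofibrosarcoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring the association between surgical resection
    margin width and local recurrence in soft-tissue sarcoma registry
    cohorts. Implements dichotomization-threshold scanning with exact
    two-by-two tests, multiplicity control by Bonferroni and by min-p
    permutation family-wise error adjustment, stratified margin-by-
    radiotherapy recurrence tables, and exploratory logistic, ROC and
    bootstrap stability analyses. Ships a canonical myxofibrosarcoma
    cohort reconstructed deterministically from published summary tables,
    and a synthetic registry-cohort generator with a measurement floor,
    missingness and confounding by indication for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
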