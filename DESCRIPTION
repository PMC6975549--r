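Package: tglasso
Title: Tissue-Guided LASSO for Preclinical-to-Clinical Drug Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts clinical drug response of tumors from sparse linear
    models trained on preclinical cancer cell lines. Implements cross-cohort
    expression harmonization (gene filtering, log transformation, empirical
    Bayes batch correction, z-scoring), tissue-guided selection of the LASSO
    penalty (TG-LASSO), two baseline strategies for including tissue of
    origin, rank-based evaluation statistics (one-sided Mann-Whitney
    separation, Fisher combined p-values, Precision@k%, odds-ratio-maximizing
    contingency analysis), gene-signature aggregation with survival
    stratification, and a synthetic paired-cohort generator with ground truth
    for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    sva,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
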