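Package: haplomark
Title: Methylation Haplotype Markers for Plasma ctDNA Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read-level methylation haplotype analysis for liquid-biopsy
    cancer detection. Computes block-level methylation haplotype measurements
    (AMF, MHL, MHL3, UMHL, UMHL3, MHFm, MHFu) over methylation haplotype
    blocks, discovers differentially methylated marker panels through
    filtered Wilcoxon contrasts, resampled cross-validated selection and
    TSS-window literature sets, builds an incremental-feature-selection SVM
    plasma classifier with KNN imputation and robust scaling, optionally
    integrates the serum marker CA19-9 by logistic regression, and provides
    the matching evaluation statistics (ROC/AUC, bootstrap and
    Clopper-Pearson confidence intervals, chi-square window screens, DeLong
    and variance-ratio AUC comparisons, exact McNemar and hypergeometric
    tests). A synthetic plasma cohort generator with read-level tumour
    fraction dilution supports end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
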