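Package: microbemr
Title: Two-Sample Mendelian Randomization, Mediation and Microbiome
    Biomarker Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for two-sample Mendelian randomization (MR) from
    GWAS summary statistics: instrument selection with p-value, linkage
    disequilibrium (LD) clumping and weak-instrument filters; allele
    harmonization with palindromic-variant handling; inverse-variance
    weighted, MR-Egger, weighted median, simple mode and weighted mode
    estimators with odds-ratio reporting; a sensitivity suite (Cochran's
    Q, Egger intercept, MR-PRESSO outlier detection, leave-one-out);
    bidirectional MR and two-step mediation with proportion mediated.
    Includes synthetic-data generators for GWAS summary statistics under
    configurable pleiotropy and for three-group case-control abundance
    cohorts, and a biomarker-evaluation stage (Kruskal-Wallis with
    eta-squared and simulated power, multiplicity adjustment, ROC/AUC
    with Youden cutoff and confusion matrix, marker combination,
    correlation with cognitive scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
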