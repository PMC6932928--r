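Package: esometh
Title: Diagnostic and Prognostic DNA Methylation Classifiers for
    Esophageal Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage analysis of Illumina 450K-style DNA methylation
    beta-values for esophageal disease. The diagnostic stage identifies
    tissue-specific CpG markers for normal squamous esophagus, Barrett's
    esophagus, esophageal adenocarcinoma and esophageal squamous cell
    carcinoma by pairwise empirical-Bayes moderated t-statistics with an
    all-pairs intersection rule against adjacent-organ tissues, then
    selects a stable marker panel by repeated-partition grouped-penalty
    multinomial lasso and fits a multinomial classifier. The prognostic
    stage screens differentially methylated CpGs with covariate-adjusted
    Cox models, selects markers by subsampled LASSO-Cox stability
    selection, and stratifies patients by the median of a Cox risk
    score. Includes a seeded synthetic-data generator with planted
    diagnostic and prognostic signal, and evaluation tools (confusion
    matrices with exact binomial intervals, micro-average one-vs-all
    ROC/AUC, Kaplan-Meier and log-rank, Cox regression tables,
    time-dependent ROC, and four-level risk stratification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    limma,
    nnet,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
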