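Package: mhbkit
Title: Methylation Haplotype Block Discovery, Haplotype Load Scoring and
    Marker-Based Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for read-level DNA methylation haplotype analysis:
    discovery of methylation haplotype blocks (MHBs) from adjacent-CpG
    linkage disequilibrium, methylated and un-methylated haplotype load
    (MHL/UMHL) scoring of samples over blocks, differential marker
    selection through a detection/variability/Wilcoxon-FDR filter
    cascade, random-forest and RBF-SVM classification with repeated
    stratified cross-validation and ROC/AUC summaries, tissue-to-plasma
    model transfer, and Kaplan-Meier/log-rank validation of predicted
    groups. Includes a synthetic cohort generator that emulates
    block-structured CpG co-methylation, tumor/normal and microvascular
    invasion contrasts, plasma dilution of tumor signal, detection
    dropout and censored survival, so the whole pipeline can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    kernlab,
    randomForest,
    Rcpp,
    stats,
    survival,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
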