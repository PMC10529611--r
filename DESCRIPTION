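Package: sgescore
Title: Variant Function Scoring and Classification for Saturation Genome Editing Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of CRISPR-Cas9 saturation genome editing (SGE)
    assays that score variant function from amplicon sequencing. Covers amplicon
    and variant-library design with HGVS coordinate mapping, a ground-truthed
    simulator of editing outcomes (HDR variants, NHEJ indels, drug-arm
    selection), paired-read merging and Needleman-Wunsch alignment with
    HDR-marker gating, pseudocounted frequency normalization and log2
    function scores, loess correction of positional editing-rate bias with
    within- and across-exon anchoring on synonymous and nonsense controls, a
    three-assay probit classifier producing probabilities of impact on
    function with perturbation confidence intervals and K-fold cross
    validation, and a supervised Gaussian-mixture classifier with
    sensitivity/specificity, likelihood-ratio, ROC/AUC and OddsPath
    (ACMG PS3/BS3) evidence calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    mclust,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
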