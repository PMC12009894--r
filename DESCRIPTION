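Package: cnbag
Title: Copy-Number Genotype Imputation from Flanking SNPs with Attribute Bagging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes gene copy-number (CN) genotypes from unphased SNP-array
    genotypes in the flanking region of a CN-variable gene, as found in the
    leukocyte receptor complex (LILRB3/LILRA6/LILRA3). A reference panel with
    known per-haplotype CN alleles is used to train an attribute-bagging
    ensemble: each classifier is fit on a bootstrap sample, greedily grows an
    informative SNP subset by out-of-bag accuracy, and models joint SNP+CN
    extended-haplotype frequencies by EM from unphased genotypes. Predictions
    average posterior CN-genotype probabilities across classifiers and apply
    a call threshold. Includes SNP quality control (MAF, call rate, exact
    Hardy-Weinberg test), PLINK bed/bim/fam and TSV input, model
    serialization, evaluation harnesses (out-of-bag and k-fold validation,
    flanking-window and call-threshold sweeps, per-class diagnostics), and a
    synthetic panel simulator with controllable SNP-CN linkage
    disequilibrium.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
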