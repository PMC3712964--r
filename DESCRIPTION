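Package: panelaug
Title: Reference Panel Augmentation for Genotype Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation pipeline for quantifying how much a
    small population-specific ("local") reference panel of phased haplotypes
    improves genotype imputation accuracy when added to a large global panel.
    Provides a synthetic structured-population generator with realistic
    linkage disequilibrium and allele-frequency drift, a sequence-data
    quality-control cascade (phred-scaled site and call filters, call rate,
    minor allele frequency, exact Hardy-Weinberg test, array-sequence
    concordance), a haploid Li-Stephens haplotype-copying hidden Markov model
    imputation engine supporting one or two reference panels, and
    leave-one-out cross-validation of per-SNP dosage r-squared with
    MAF-binned summaries and effective-sample-size conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
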