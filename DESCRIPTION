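Package: rsnpscan
Title: Prediction of Promoter Regulatory SNPs from Allele-Aware Motif Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts regulatory single-nucleotide polymorphisms (rSNPs) in
    proximal promoters. Builds allele-aware 2 kb pseudo-promoters from a
    reference genome and a common-SNP catalogue, scans both strands with
    JASPAR-style position weight matrices, gates candidate SNPs by per-cell-line
    chromatin accessibility, and scores each SNP-transcription-factor pair with
    a relative binding score for both alleles, the percent affinity impact,
    homotypic redundancy and its weight factor, and a functional impact factor
    (FIF). Includes evidence-aggregation rules for confirming predicted rSNPs
    against externally produced annotation scores (GWAVA, FunSeq2, DeepSEA,
    eQTL m-values, expression levels), a seeded synthetic-data generator with
    planted ground truth, and packaged study tables from a Fabry-disease
    modifier-gene panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    optparse,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
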