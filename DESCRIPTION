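Package: imputeval
Title: Genotype Imputation Accuracy Evaluation by Masking Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify genotype-imputation accuracy from a SNP-array
    panel up to whole-genome-sequence density. Provides a deterministic
    synthetic-population simulator (ancestral-mosaic haplotypes, rare-variant
    skewed site frequency spectrum, array-site ascertainment, sequencing-style
    genotype artifacts), GATK-style site and genotype quality-control filters,
    reference-animal selection by k-means clustering of the genomic
    relationship matrix, two built-in imputation engines (a Li-Stephens
    haplotype-copying hidden Markov model and an overlapping-sliding-window
    haplotype matcher), and a masking fivefold cross-validation harness that
    reports per-animal and per-SNP squared-correlation and concordance
    accuracy, stratified by minor allele frequency, functional-impact class
    and 1-Mb genomic window, together with model-based Rsq calibration curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
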