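Package: feedomics
Title: Multi-Omics Identification of Functional Variants for Feed Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for locating candidate functional variants
    behind quantitative-trait GWAS signals by integrating chromatin
    accessibility and gene expression. Implements phenotype quality control
    of growth records, variant-level genotype QC and imputation-concordance
    assessment, a mixed-linear-model association scan with
    leave-one-chromosome-out genetic relationship matrices (REML variance
    components via eigendecomposition), negative-binomial differential
    testing for RNA-seq and ATAC-seq count matrices, and an integration
    stage that intersects genome-wide-significant SNPs with differential
    open-chromatin regions, assigns candidate genes within topologically
    associated domains, and validates variants by genotype-class phenotype
    comparison. A synthetic-data generator with planted truth makes every
    stage recovery-testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
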