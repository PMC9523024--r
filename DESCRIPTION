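Package: gxescan
Title: Genotype-by-Environment Interaction GWAS with Two-Kernel Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide association scans of genotype-by-environment
    (GxE) interaction in inbred crop panels, motivated by temperature-dependent
    seed germination in rice. Provides variant preprocessing from VCF
    (heterozygote masking, tri-allelic to bi-allelic expansion, minor allele
    frequency / mapping quality / call-rate filters), genomic relationship
    matrices and principal-component covariates, EMMA-style single-kernel
    variance-component estimation and narrow-sense heritability,
    per-environment linear mixed-model association scans, a per-marker
    likelihood-ratio test of environment-specific marker effects under a
    two-kernel mixed model whose GxE covariance is a Hadamard product of the
    kinship and environment-incidence kernels, local linkage-disequilibrium
    matrices, haplotype grouping with minimum-spanning-network construction,
    and a seeded synthetic-data generator that reproduces the statistical
    structure assumed by the models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
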