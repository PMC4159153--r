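Package: EpistasisScan
Title: Genome-Wide SNP-SNP Interaction Discovery for Quantitative Traits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for discovering pairwise epistatic interactions
    affecting a quantitative trait in population cohorts. Implements genotype
    and sample quality control, GRAMMAR-style polygenic residualization of the
    trait against a genomic kinship matrix, a bit-packed exhaustive pairwise
    interaction scan with Bonferroni threshold derivation and local-interaction
    classification, conditional testing with forward selection and cumulative
    variance-explained accounting, and regulatory enrichment statistics
    (enhancer-overlap binomial tests against a genotyped-SNP background and
    chromatin-interaction counting around trait-associated regions). Includes
    a synthetic-cohort generator with LD-structured genotypes, planted marginal
    and epistatic effects and annotation tracks, so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GenomeWideAssociationStudies, SNP, Epistasis, QualityControl,
    StatisticalMethod
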