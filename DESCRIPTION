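Package: breedsig
Title: Breed-Specific Genetic Signature Discovery from Multi-Breed
    Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Discovers breed-specific genetic signatures from phased
    multi-breed genotype panels. Implements mutual-information based
    discriminative SNP selection on adjacent-locus haplotypes, weighted
    mutual-information (wMI) gene scoring with permutation significance,
    cross-population selection scans (XP-EHH and a simplified XP-CLR-style
    windowed allele-frequency differentiation scan) with SNP-count-binned
    empirical p-values, per-chromosome Fisher enrichment and
    dominant/recessive/co-dominant case-control tests, and gene-gene
    correlation networks built from genotype zygosity profiles. Ships a
    seeded multi-breed genotype simulator (Balding-Nichols drift with
    planted signature genes and selective sweeps) so the whole workflow is
    testable end to end without external data.
License: MIT
Encoding: UTF-8
Imports:
    GenomicRanges,
    igraph,
    IRanges,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
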