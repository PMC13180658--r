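Package: scPRS
Title: Single-Cell-Resolved Polygenic Risk Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes a polygenic risk score (PRS) into per-cell scores by
    conditioning clumping-and-thresholding on single-cell chromatin
    accessibility, integrates the resulting cell-level risk features with a
    nonnegativity-constrained graph neural model over a mutual k-nearest
    neighbour cell graph, and interprets the learned per-cell readout weights
    to prioritize disease-relevant cells, cell types, regulatory elements and
    variants. Includes quality control and allele harmonization for GWAS
    summary statistics and target genotypes, model-agnostic variant effect
    Z/Q scores, enrichment statistics, a covariate-adjusted differential
    accessibility test, and a coupled genotype-atlas-phenotype simulation
    framework so that the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
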