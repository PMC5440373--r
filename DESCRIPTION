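Package: condconj
Title: Conditional and Conjunction FDR Analysis of Cross-Trait
    Pleiotropy from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies genetic loci shared between two complex traits
    from genome-wide association study (GWAS) summary statistics alone.
    Implements conditional Q-Q and fold-enrichment stratification of one
    trait's p-values on the other's significance, empirical-Bayes
    conditional and conjunction false discovery rates (cfdr/conjFDR) on a
    two-dimensional significance grid, genomic-control inflation
    correction, LD-aware random pruning, region exclusion and greedy
    clumping, locus definition with nearest-gene annotation and
    effect-direction concordance, and substudy-based stratified
    replication-rate curves. Includes a seeded simulator of paired
    polygenic summary statistics with block LD structure, extended-LD
    regions and substudy panels, so the whole pipeline can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
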