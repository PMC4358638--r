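Package: cnvclust
Title: Network Cluster Enrichment for Population-Differential Copy-Number
    Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions a gene/protein interaction network into clusters with
    the Markov Cluster (MCL) algorithm across a sweep of inflation values,
    maps copy-number variants (CNVs) and disease-associated SNPs to genes by
    genomic-coordinate overlap, repartitions CNVs into population-preferred
    sets by a majority-occurrence rule, scores every cluster for joint
    enrichment of pathogenic genes and population-preferred CNV genes with
    right-tailed Fisher's exact tests and a robust (pi0-based) false
    discovery rate, groups similar clusters across inflation runs into
    families, and tallies how often each family ranks first, nominating
    candidate gene modules for health disparities. A seeded synthetic-data
    generator with planted ground truth makes the whole pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
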