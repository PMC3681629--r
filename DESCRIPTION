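Package: dhsvar
Title: Detection and Genetic Analysis of Variable DNase I Hypersensitive
    Sites Across Inbred Mouse Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls DNase I hypersensitive sites (DHS) from per-base
    sequencing coverage using a coverage-adjusted log transform and
    maximal high-scoring segment detection, identifies peaks whose
    heights vary heritably between inbred mouse strains with a
    negative-binomial likelihood-ratio test and variance-components
    heritability, classifies variable peaks into continuous, discrete
    and compound-discrete modes, associates peaks with sequence
    variants through strain distribution patterns and position-weight-
    matrix motif disruption, links peaks to strain-variable transcripts,
    and tests feature and QTL-candidate enrichment with exact
    contingency tests. Includes a negative-binomial synthetic-data
    generator with planted ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
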