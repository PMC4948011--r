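Package: synqtl
Title: Synteny Mapping, Rearrangement Calling and QTL Orthology for Solanaceae Genome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics pipeline for pairs of related plant
    genomes: filtering and deduplication of CDS and marker alignment hits
    (GMAP-style GFF3 and tabular BLAST), validation of primer-pair marker
    anchors, chaining of anchors into orientation-consistent synteny blocks,
    classification of chromosomal rearrangements (inversions, translocations,
    transpositions, duplications), projection of genetic-map QTL confidence
    intervals onto physical coordinates via local bp/cM rates, and detection
    of orthologous QTL clusters between two species on a shared reference
    genome. Includes a ground-truth simulator of rearranged genome pairs,
    genetic maps and QTL so every stage can be validated without external
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    ggplot2,
    rlang,
    yaml,
    jsonlite,
    withr,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
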