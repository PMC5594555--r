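Package: famscan
Title: Annotation and Evolutionary Analysis of Expanded CEA/PSG Gene Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for discovering, classifying and evolutionarily analyzing
    expanded carcinoembryonic antigen (CEA) gene families in genome contigs:
    homology-seeded exon mining with splice-site validation, gene-model assembly,
    receptor versus pregnancy-specific glycoprotein (PSG) architecture
    classification, immunoreceptor tyrosine-based motif (ITIM/ITSM/ITAM)
    detection, neighbor-joining phylogenetics with bootstrap support, and
    counting-based (Nei-Gojobori / SLAC-style) positive-selection analysis.
    Includes a synthetic-genome generator that plants CEA-family gene cassettes
    with a machine-readable truth set so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    yaml,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
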