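Package: mitopanel
Title: Multi-Locus Mitochondrial Mini-Barcode Species Identification from
    Nanopore Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end engine for vertebrate species identification from
    basecalled nanopore reads of a tetraplex mitochondrial mini-barcode panel
    (CYTB, COI, 16S and 12S rRNA). Models rapid-kit tagmentation read
    structure, performs quality/length filtering, sample-index demultiplexing
    and distal-end primer assignment, greedy clustering and strand-wise
    consensus building, local-alignment search against a local reference
    database with BLAST-style tabular output, and rule-based single-source or
    mixture species calling with nuclear-pseudogene (numt) flagging. Includes
    a neighbour-joining Kimura two-parameter workflow for assessing the
    species-discrimination power of a barcode panel, and a full synthetic-data
    generator for amplicons, tagmented indexed reads and ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
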