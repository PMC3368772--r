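Package: mirforge
Title: Small RNA Sequencing Analysis and MicroRNA Discovery for Plant Transcriptomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for plant small RNA sequencing libraries:
    adapter trimming and collapsing of raw reads, categorization of unique
    small RNAs against annotated reference sets, assignment to conserved
    microRNA families, hairpin-based discovery of miRNA precursors under
    structural rules (free-energy bound, bounded unpaired duplex positions,
    miR-miR* distance window) with a five-class precursor taxonomy,
    detection of single-nucleotide editing and 5' trimming / 3' uridylation
    isoforms, and penalty-scored miRNA target prediction with canonical
    cleavage-site calling. Includes a deterministic synthetic-data generator
    with planted ground truth so the whole pipeline is testable without
    external downloads. Secondary-structure prediction uses a shipped
    nearest-neighbour energy model with an exact dynamic program.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
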