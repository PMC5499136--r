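Package: triplexmap
Title: Genome-Wide Mapping of Putative DNA:RNA Triplexes
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts and analyses putative DNA:RNA triple helices on a
    genome-wide scale. Detects triplex-forming oligonucleotides (TFOs) in
    transcript sequences and triplex-target sites (TTSs) in duplex DNA as
    maximal runs under the Hoogsteen base-pairing motifs, enumerates all
    maximal zero-mismatch TFO:TTS matches in purine space, removes trivial
    self-matches, merges overlapping matches into sites, and summarises
    their genomic distribution (localization tables, chromosome bins,
    length-normalised gene and transcript densities with cumulative-share
    selection of triplex-enriched genes). Also estimates TFO structural
    accessibility from intramolecular hairpin and long-range pairings,
    performs hypergeometric Gene Ontology over-representation tests, and
    decomposes genetic-interaction networks among enriched genes into
    overlapping clique-agglomerated modules. A synthetic-data generator
    with planted, fully known triplex structure makes the whole pipeline
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
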