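Package: circbiofluid
Title: Multi-Tool Consensus Detection and Characterization of Circular RNA in Biofluids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes back-splice junction calls from six circular RNA
    (circRNA) detection tools (CIRCexplorer, CIRI2, DCC, find_circ, KNIFE,
    MapSplice) into a single zero-based coordinate convention, applies
    read-support and sample-recurrence detection filters, derives the
    strict multi-tool consensus catalog, quantifies circRNA expression as
    junction reads per million (JRPM) and as the circular-to-linear ratio
    (CLR) against flanking linear splice junctions, annotates junctions
    with genomic features from BED12 transcript models, and assesses
    longitudinal within-participant expression stability by coefficient
    of variation. Includes a ground-truthed synthetic data generator that
    emits per-sample caller outputs in every native dialect so the full
    pipeline is verifiable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
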