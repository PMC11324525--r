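Package: aavint
Title: AAV Vector Integration Analysis from Short- and Long-Read Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterization of adeno-associated virus (AAV)
    vector integration in host genomes. Implements anchored-PCR (ITR-seq)
    junction calling with UMI/adapter-position separation of cell clones from
    PCR duplicates and per-100-genomes normalization; annotation of
    integration sites against gene models, liver-expression categories and
    cancer-gene lists with fold-change enrichment over a random-locus
    background; and structural annotation of long consensus reads containing
    episomal or integrated vector concatemers (segment decomposition,
    junction configurations, ITR integrity, functional-cassette detection,
    flank integrity). Ships a synthetic-data module that forges toy host and
    vector genomes and reads with complete planted ground truth, so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
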