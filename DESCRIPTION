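Package: spliceEvo
Title: Comparative Analysis of Splicing-Factor-Dependent Exon Programs
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to identify splicing-factor-dependent alternative splicing
    events and differentially expressed genes from percent-spliced-in (PSI) and
    read-count tables, to cluster homologous alternative exons across species
    using intron-position/phase-aware protein alignments, to build
    position-resolved RNA regulatory maps from hexamer motif coverage, to
    classify direct versus indirect splicing-factor targets under restricted or
    expanded positional scenarios, and to summarise cross-species conservation
    of exon regulation. Includes a synthetic-data generator that simulates
    multi-species gene families, replicate PSI tables with planted effects and
    binomial read noise, planted motifs and smooth conservation tracks with
    known ground truth, so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: AlternativeSplicing, RNASeq, Transcriptomics, ComparativeGenomics
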