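Package: mpba
Title: Analysis of Massively Parallel Binding Assay Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing massively parallel binding
    assay (MPBA) experiments, in which a transcription-factor-MNase fusion
    cleaves plasmid-borne regulatory-region variants so that read depletion
    after nuclease activation reports transcription-factor occupancy.
    Provides combinatorial motif-mutation library design (all 2^n
    intact/mutated motif combinations of a regulatory region), assignment of
    amplicon reads to library variants with an indel filter, the
    normalization chain from raw counts to per-variant occupancy fractions,
    motif-interaction statistics (pairwise cooperativity against an
    independence null, non-cooperative recruitment, self-motif region
    occupancy, TF-pair occupancy correlation), k-mer relative-binding
    enrichment from genomic signal tracks, nucleosome-occupancy rescaling
    against a genomic anchor, and a generative simulator of the assay with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcription, MotifAnnotation, Sequencing, Software
RoxygenNote: 7.3.3
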