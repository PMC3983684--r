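Package: hypoxtx
Title: Integrative Analysis of the Hypoxic Coding and Non-Coding Transcriptome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for integrative analysis of hypoxia-regulated transcription:
    priority-based assignment of transcribed features to RNA classes with
    class-specific abundance filtering, class-wise fold-change summaries,
    discovery and classification of non-annotated intergenic and antisense
    transcripts (with CpG-island detection and an ORF-based coding-potential
    score), assignment of HIF ChIP-seq peaks to the nearest expressed promoter,
    a weighted running-sum gene-set enrichment statistic with a permutation
    null, and RNA polymerase II promoter-pausing analysis (metagene profiles,
    travelling ratios, and classification of hypoxic induction into
    pause-release versus de novo recruitment). A seeded simulator generates
    miniature genomes, annotations, count matrices, HIF peak sets and coverage
    tracks with planted, recoverable effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
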