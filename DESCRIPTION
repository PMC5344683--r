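Package: cracr
Title: Analysis of CRAC Protein-RNA Crosslinking Sequencing Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational analysis of CRAC (UV crosslinking
    and analysis of cDNAs) sequencing experiments profiling RNA polymerase II
    and nuclear RNA surveillance factors. Covers linker-aware FASTQ
    preprocessing with random-trimer PCR-duplicate collapsing, alignment with
    capture of crosslink-induced single-nucleotide deletions and
    non-genome-encoded 3' additions, oligo(A) tail classification,
    per-transcript quantification with hits-per-million scaling and
    factor-to-polymerase occupancy ratios, directional fold-change
    clustering, microdeletion-based crosslink-site calling with consensus
    motif scoring, anchored and length-normalized metagene profiles, and
    spliced-to-unspliced junction ratios. Includes a synthetic-data
    generator that plants every signal the pipeline detects, with
    machine-readable truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    ShortRead,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
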