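Package: tetrasite
Title: Discovery of Transcription-Factor Tetramer-Specific Binding Sites by
    Genotype-Contrast ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for locating STAT5 tetramer-specific genomic binding sites
    by contrasting ChIP-seq of a wild-type (dimer- and tetramer-competent)
    genotype against a tetramer-deficient knockin genotype. Provides a
    Poisson sliding-window peak caller with a locally estimated background,
    GAS motif scanning with tandem-pair spacing analysis, peak-to-gene
    annotation by the 5-kb-upstream-plus-gene-body rule, RPKM-based
    differential expression across NK-cell maturation subsets, and
    integration of lost binding with reduced expression to nominate direct
    tetramer target genes. A synthetic-data module generates genomes with
    planted GAS motifs, genotype-asymmetric ChIP coverage and
    stage-structured count tables with full ground truth, so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
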