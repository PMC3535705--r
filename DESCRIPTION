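Package: methcapr
Title: Quality Control, Differential Methylation and Global Methylation
    Estimation for MethylCap-seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-alignment analysis of MBD-capture (MethylCap-seq)
    sequencing experiments. Builds a CpG index and fixed-width bin grid
    from a reference genome; loads per-lane single-end alignments from SAM
    or BED, removes duplicate alignments, extends reads to fragment length
    and counts them into 500-bp bins normalized to reads per million;
    computes lane-level quality control metrics (CpG enrichment,
    saturation, 5x CpG coverage, zero-CpG-bin noise) with exclusion
    thresholds; calls differentially methylated regions by feature-level
    Wilcoxon rank-sum tests with Benjamini-Hochberg false discovery rate
    control; estimates a global methylation indicator from the CpG-density
    methylation distribution and validates it against a fully methylated
    spike-in construct; and bundles an MBD-capture simulator with known
    truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
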