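Package: tagbench
Title: Benchmarking Untargeted Tn5 Tagmentation Background in Targeted
    CUT&Tag Peak Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how untargeted Tn5 tagmentation at
    accessible chromatin confounds peak calling and differential
    enrichment in targeted CUT&Tag experiments (for example G-quadruplex
    mapping assays). Provides a synthetic tagmentation data generator
    with accessibility-driven background, targeted capture and PCR
    duplication; library-complexity estimation from duplication
    histograms with ratio-based downsampling; binned coverage tracks,
    FRiP scores and peak count matrices; a simplified sparse-enrichment
    (SEACR-style) peak caller in threshold and control modes;
    interval-set benchmarking with consensus derivation,
    precision/recall/F1, Jaccard, width-preserving shuffled nulls and
    Fisher association; and a negative-binomial Wald test for
    differential read-count enrichment at peaks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
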