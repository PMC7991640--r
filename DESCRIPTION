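Package: chiprx
Title: Spike-In Normalized ChIP-Seq Analysis of Histone Mark and Enhancer Reprogramming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of reference-adjusted (spike-in normalized)
    ChIP-seq experiments that profile histone H3K36 methylation and enhancer
    chromatin states, as used to study oncohistone (H3K36M) mutant cells.
    Provides genomic interval algebra with shuffled-null backgrounds, ChIP-Rx
    normalization to reference-adjusted reads per million (RRPM), per-interval
    density and scaled metagene profiling, enhancer calling and
    active/primed/poised classification with enhancer-to-gene assignment,
    peak-set decomposition and genomic-element annotation, correlation of mark
    changes with mutant-histone occupancy, and a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
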