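Package: h3profiler
Title: Histone Variant Enrichment Profiling from Genomic Density Tracks
Version: 1.0.0
Authors@R:
    person("h3profiler", "developers", email = "h3profiler@example.org",
           role = c("aut", "cre"))
Description: Genome-wide analysis of histone variant (H3.3/H3.1) ChIP density
    tracks: anchored aggregate profiles over centromeres, point sites and genes
    (TSS/TTS half-gene alignment with flanking inter-annotation regions);
    expression- and length-stratified metagene profiles; last-kilobase 3'
    enrichment statistics with tie-averaged Spearman rank correlation against
    expression; chromatin-state and feature-class signal distributions;
    replicate-consistency filtering of FPKM tables; a deterministic
    synthetic-data generator with recorded ground truth; and an end-to-end
    pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    tools,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
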