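# h3profiler

Genome-wide analysis of histone variant enrichment from ChIP density
tracks, for chromatin biologists studying replication-independent H3.3
versus replication-coupled H3.1 deposition.

Plant and animal H3.3 variants share a diagnostic genomic signature:
enrichment over actively transcribed gene bodies with a bias towards the
transcription termination site (TTS), depletion from constitutive
heterochromatin, and dynamic redistribution when the transcriptome is
remodelled (for example when cells stop dividing and differentiate).
`h3profiler` packages the complete analysis that establishes this
signature from fixed-step density tracks, together with a synthetic-data
generator that encodes the expected biology with recorded ground truth, so
every statistic in the pipeline can be validated end to end without the
original sequencing data.

## What it computes

* **Aggregate (metagene) profiles.** For anchors `a_1..a_n` and a
  normalized density `s(x)`, the profile at bin offset `o` is
  `P(o) = mean_i  s̄[a_i + o, a_i + o + b)` over the anchors whose window
  reaches that bin (minus-strand anchors are coordinate-reversed), followed
  by a centered sliding mean. Three anchor modes: point anchors
  (centromere centers, 200-kb bins over 20 Mb, 1-Mb smoothing; TFBS-like
  sites, 50-bp bins over 2 kb, 200-bp smoothing) and the dual-anchored
  half-gene mode, which aligns each gene's 5′ half at the TSS and 3′ half
  at the TTS in 50-bp bins together with the flanking inter-annotation
  regions.
* **Annotation arithmetic.** Inter-annotation regions (complement of all
  features, kept when > 150 bp), chromatin-state segment merging, and the
  standard gene exclusions (organellar, overlapping another annotation,
  shorter than 1 kb).
* **Expression handling.** FPKM tables per (tissue, replicate); the
  three-rule replicate-consistency filter (|Δ| > 1 FPKM, Δ/min > 1/3, or
  zero in exactly one replicate); expression bins (FPKM > 30 … 0–1) and
  length bins; ≥ 5-fold differential and ON (> 3) / OFF (< 1) gene sets;
  per-group expression totals and dividing/non-dividing ratios.
* **Enrichment statistics.** Last-1-kb 3′ enrichment (mean normalized
  signal over the kilobase upstream of the TTS in gene orientation),
  tie-averaged Spearman rank correlation against expression, 10-gene and
  500-gene sliding-window scatter series, per-class five-number summaries,
  and the two-sided Welch t-test.
* **Synthetic data.** Deterministic generator for genomes (centromeres,
  heterochromatic knobs, non-overlapping stranded genes, TEs biased into
  heterochromatin), chromatin states, two-tissue/two-replicate FPKM tables
  with a controlled differential fraction, and per-tissue tracks for
  H3.3 / H3.1 / H3 / IgG with Poisson sampling noise.

## Worked example

```r
library(h3profiler)

cfg <- synthetic_config(seed = 1)          # 5 x 1 Mb chromosomes, 1000 genes
sim <- simulate_dataset(cfg)

pool <- function(tissue, ab)
  average_replicates(lapply(sim$tracks[[tissue]][[ab]],
                            normalize_by_library_size))
h33 <- pool("dividing", "H3.3"); h31 <- pool("dividing", "H3.1")

filt  <- filter_genes_for_profiles(sim$features[sim$features$category == "gene", ],
                                   sim$features)
verd  <- filter_expression(sim$expr)
means <- expression_means(sim$expr)
genes <- filt$kept[filt$kept$id %in% verd$gene_id[verd$keep], ]
genes <- genes[genes$id %in% means$gene_id[means$expressed] &
               genes$end - genes$start >= 1000, ]
mm <- means[match(genes$id, means$gene_id), ]

rho33 <- spearman_correlation(last_kb_enrichment_table(h33, genes)$value,
                              mm$dividing)
rho31 <- spearman_correlation(last_kb_enrichment_table(h31, genes)$value,
                              mm$dividing)
cat(sprintf("genes profiled: %d\nSpearman rho: H3.3 %.2f, H3.1 %.2f\n",
            nrow(genes), rho33, rho31))
#> genes profiled: 757
#> Spearman rho (last kb vs FPKM): H3.3 0.98, H3.1 0.01
```

The H3.3 last-kb enrichment tracks expression almost perfectly in the
noise-limited synthetic world, while H3.1 is uncorrelated — the qualitative
signature the pipeline is built to detect. The half-gene profile shows the
3′ ramp directly (mean enrichment rising as offsets approach the TTS at 0):

```r
irs <- compute_inter_annotation_regions(sim$features, sim$genome, min_len = 150)
pr  <- halfgene_profile(h33, genes, gene_flanks(genes, irs),
                        bin = 50, max_extent = 1500, smooth = 500)
tail(pr[pr$segment == "3half", ], 3)
#>    segment offset     mean     n
#> 1:   3half   -150 2.935195   757
#> 2:   3half   -100 2.949349   757
#> 3:   3half    -50 2.963476   757
```

and chromatin-state distributions show the CS3 (heterochromatin) depletion
of H3.3 (median 1.89 in CS3 vs 2.82 in active CS1; configured depletion 0.5):

```r
distribution_over_regions(h33, sim$states, by = "state")
#>     class       min       q1   median       q3      max     n
#> 1:    CS1 1.8547978 2.547858 2.815291 3.106928 4.431595   617
#> 2:    CS2 1.8746547 1.988363 2.053011 2.132218 3.279735   383
#> 3:    CS3 0.9439421 1.874061 1.888236 1.898863 1.923416    70
#> 4:    CS4 1.7023420 1.875366 1.898551 1.922835 2.048783  1075
```

## Command line

```sh
Rscript inst/scripts/h3profiler simulate --seed 7 --out data/
Rscript inst/scripts/h3profiler run-all --config run.json
Rscript inst/scripts/h3profiler enrichment --config run.json   # one stage
```

`run.json` names a dataset directory and output directory plus parameter
overrides; every analysis parameter (bins, spans, smoothing, thresholds)
is surfaced with its conventional default (see `default_params()`). A full
run writes TSV/JSON outputs for every stage and a `manifest.json`
recording the 8 completed stages and the config hash; reruns with the same
config and seed are byte-identical.

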