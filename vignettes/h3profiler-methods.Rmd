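---
title: "Methods: histone variant enrichment profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histone variant enrichment profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`h3profiler` implements the standard genome-wide comparison of a
replication-independent histone variant (H3.3) against its
replication-coupled counterpart (H3.1), starting from fixed-step ChIP
density tracks rather than raw reads. The biological questions it is
built around are: where along genes is H3.3 deposited, how strongly does
that deposition track transcription, how do the two variants partition
between chromatin states, and how does H3.3 redistribute when the
transcriptome is remodelled between a dividing and a non-dividing tissue.

All coordinates inside the package are 0-based half-open. GFF3 input is
converted on read; BED passes through; emitters convert back. A single
frame removes a whole class of off-by-one errors from the interval
arithmetic that the analysis leans on (complements, abutment tests,
anchored windows).

# Signal model and normalization

A `SignalTrack` holds one value per fixed `step` window (10 bp by
default), interpreted as a per-base density constant within the window —
the semantics of a peak caller's density output, which is why positions
absent from a file are 0 and not `NA`. bedGraph and variableStep input is
resampled onto the step grid by coverage-weighted mean. Tracks are made
comparable by one global multiplication, `scale / mapped_reads` with
`scale` = 1e6 (per million mapped reads); the scale constant is exposed
because only the ratio between libraries matters. Interval means are
coverage-weighted (partial step bins count by overlap length), computed
from a cumulative integral so they equal the per-base mean exactly; the
test suite asserts this equality against literal per-base oracles at
1e-9.

Where a condition was assayed in replicates, replicate tracks are
normalized individually and averaged element-wise before analysis. The
original design used one pooled track per condition; whether that meant a
single library or a replicate mean is not decidable from the text, so the
pipeline defaults to the replicate mean and accepts single replicates.

# Aggregate profiles

The profiling engine has two modes.

**Point-anchored.** Windows of `span` bp in `bin`-bp bins centered on each
anchor; minus-strand anchors are coordinate-reversed so profiles read
5′→3′. Anchors whose window runs off a chromosome end contribute the bins
that exist rather than being dropped: with 20-Mb centromere windows, any
dropped-anchor rule would discard most anchors on a test-scale genome,
and for full-size genomes the two rules agree wherever the window fits.

**Half-gene (TSS/TTS dual-anchored).** Each gene contributes four
segments: its 5′ flanking inter-annotation region, the 5′ half of the
body anchored at the TSS, the 3′ half anchored at the TTS, and the 3′
flanking IR. The split rule is not stated in the original description;
here each half extends `floor(length/2)` rounded down to a bin multiple,
so the two halves are equal and a possible odd middle base is simply not
sampled. Flank sampling stops at the end of the abutting IR (the next
annotation), and each segment is capped at `max_extent`. Per-bin means
are taken over the genes that reach the bin, so the anchor count `n`
decays with |offset| as shorter genes and flanks drop out; the suite
checks `n` bin-by-bin against the count of genes whose half-length
reaches the offset.

Profiles are finished with a centered sliding mean whose window shrinks
at the edges (output length equals input length). The source description
prescribes 1 Mb smoothing for the 200-kb-binned centromere profile and
"5 kb" for the 50-bp-binned gene profiles; a 100-bin smoother would
erase the fine 3′ structure that the gene profiles exist to show, so the
package treats the gene smoothing width as a parameter, default 500 bp
(10 bins), and makes no guess about the intended value.

# Gene filtering

Before profiling, genes are excluded if (in this precedence) they sit on
an organellar chromosome (configurable name list, default
ChrM/ChrC/mitochondria/chloroplast — the exclusion is stated by biology,
not mechanism), intersect any other non-IR annotation by at least one bp
(strand-blind; the overlap predicate is not defined in the source, so the
most conservative one is used and per-gene reasons are recorded to keep
alternatives auditable), or are shorter than 1 kb. Expression-based
analyses additionally require FPKM > 0 in at least one library and
passage of the replicate-consistency filter: a gene is discarded when, in
either tissue, (i) the absolute replicate difference exceeds 1 FPKM, or
(ii) the difference exceeds a third of the smaller replicate (evaluated
only when both are positive), or (iii) exactly one replicate is zero.
The three rules combine with OR; the reporting precedence i → ii → iii
follows the order they are stated in.

# Enrichment statistics

The summary statistic for 3′ deposition is the mean normalized signal
over the last 1 kb of the gene in gene orientation. It is correlated with
per-tissue mean FPKM by Spearman rank correlation with average ranks on
ties (Pearson on tie-averaged ranks). Scatter series smooth both
coordinates with sliding windows after ordering — 10 genes for
enrichment-vs-enrichment scatters, 500 genes for the
differential analysis, where the per-gene expression difference and
enrichment difference (dividing − non-dividing) are each converted to
tie-averaged ranks, ordered by the expression rank, and smoothed.
Distribution summaries over region classes use type-7 (linear
interpolation) quantiles — the plotting default the original analysis
delegated to without naming. Group tests use the Welch unequal-variance
t-test, two-sided, with no multiple-testing correction anywhere (none was
applied originally). Boundary conventions for stratification:
expression bins are `(lo, hi]` at 1/5/10/20/30 FPKM; length bins are
`[lo, hi)` at 1–4 kb, which is what the documented boundary examples
(1000 bp → "1–2 kb", 4500 → ">4 kb") force.

# The synthetic world

The generator emulates, at reduced scale, the features of the real system
that the statistics consume:

* **Genome** — 5 chromosomes of 1 Mb (vs five chromosomes of ~20–30 Mb in
  the real genome), each with a central centromere block (12%) and one
  50-kb heterochromatic knob; both are CS3 heterochromatin.
* **Annotation** — 1000 non-overlapping stranded genes with log-normal
  lengths (median 1.8 kb, sdlog 0.45 — matching a compact plant genome's
  gene-length scale), separated by exponential-plus-minimum gaps (mean
  400 bp) that become the flanking IRs; 300 TEs, 80% placed inside
  heterochromatin; 2000 TFBS-like point sites in the remaining IR space.
* **Expression** — a 60/40 mixture of active (log-normal, median 10 FPKM)
  and lowly-expressed genes, 5% silent; 10% of genes are at least 5-fold
  differential between tissues with random direction; replicates are the
  truth times multiplicative log-normal noise. The noise sdlog defaults
  to 0.02, chosen so the three-rule consistency filter discards ≈10% of
  genes — the discard rate the filter is known to produce on real data.
  Larger values make the absolute-difference rule (i) discard most
  well-expressed genes, which would misrepresent the filter's intended
  severity.
* **Tracks** — per-base expected densities: H3.3 is
  `baseline + slope·log(1+FPKM)·frac` along each gene (`frac` = fractional
  position 5′→3′), times a 0.5 depletion factor in heterochromatin; H3.1
  is flat with a mild 1.05 heterochromatin enrichment (kept within the
  ~uniform behaviour the variant shows across chromatin states); H3 is
  flat with a 1.3 centromeric bump; IgG is flat. Densities are averaged
  onto the 10-bp grid and Poisson-sampled at `depth` = 50 expected counts
  per unit density per bin (≈9% bin-level noise, negligible after
  averaging over genes or kilobases); the Poisson choice is the simplest
  variance-equals-mean model for count-derived densities and can be
  switched off for exact tests.

Everything is a pure function of (config, seed), and ground truth (true
FPKM, differential labels, deposition slopes) is recorded.

What the generator does **not** model: read-level artefacts (mappability,
fragment-size effects, GC bias), isoform structure, promoter-proximal
signal features, or any coupling between H3.1 and replication timing. A
green recovery test therefore establishes that the pipeline's statistics
detect the encoded relationships at realistic noise — not that they would
be robust to alignment artefacts absent from the simulation.

# Numerical and design notes

* Smoothing windows are capped at the series length per segment, so short
  profile segments never error; `sliding_mean` itself rejects windows
  above twice the series length.
* In half-gene aggregates, bins at extreme offsets are supported by few,
  long genes, and the aggregate there mixes composition change with the
  per-gene ramp; near the `max_extent` edge the profile can be locally
  flat to weakly non-monotone under sampling noise. The monotonicity
  recovery check runs at the default extent and fixed seed, where the
  aggregate ramp dominates.
* Ties in scatter sorting are broken by stable input order; this affects
  only window composition, never the correlation properties.
* Fold-change sets treat a zero denominator as exceeding any fold, so
  ON→OFF genes (the strongest movers) belong to the differential sets.
* IR minimum length is a strict inequality (> 150 bp), matching the
  documented count convention.
* The worked-example expression table (`example_h3_expression()`)
  reproduces published per-tissue mean FPKMs for the H3 variant and
  chaperone genes; two printed group totals differ from the per-gene sums
  by 0.1 FPKM (rounding in the published per-gene values), so the
  acceptance check verifies the totals that are reproducible from the
  per-gene values and derives the remaining ratio from the printed totals
  row itself.

# Limitations

The package analyses density tracks; it does not call peaks, estimate
FPKM from reads, or model isoforms — expression tables and tracks are
inputs. Real-data headline correlations depend on the deposited
sequencing libraries and are out of scope for the test suite, which
instead establishes oracle-equivalence of every operation and recovery of
the encoded biology from the synthetic world.
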