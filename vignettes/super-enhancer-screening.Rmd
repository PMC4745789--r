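---
title: "Super-enhancer screening and integrative dependency analysis with sescreen"
author: "sescreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-enhancer screening and integrative dependency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sescreen)
```

# The analysis

Ewing sarcoma is driven by the EWS/FLI1 fusion transcription factor rather
than by recurrent kinase mutations, which makes the tumor's *epigenetic*
circuitry — and in particular its super-enhancers — a natural place to look
for dependencies. `sescreen` implements the integrative screening workflow
for this setting as a tested pipeline:

1. **Super-enhancer calling.** H3K27Ac ChIP-seq peaks are filtered to
   distal enhancer candidates (away from TSSs and not promoter-like by
   H3K4me3), stitched into enhancers, quantified on a reads-per-million
   (RPM) signal track, and ranked. The characteristic hockey-stick of the
   rank-vs-signal curve separates a small set of broad, signal-rich
   super-enhancers (SEs) from the bulk of typical enhancers (TEs).
2. **Gene assignment.** Transcriptionally active genes are linked to
   enhancers whose boundary lies within a window of the gene TSS,
   producing disjoint SE-associated and TE-associated gene sets.
3. **Sequence enrichment.** GGAA microsatellites (the EWS/FLI1 binding
   element, scanned on both strands as GGAA/TTCC tandem runs) and
   EWS/FLI1 ChIP peaks are tested for enrichment in SEs versus TEs with
   Fisher's exact test; repeat counts of runs inside versus outside FLI1
   peaks are compared with Welch's t-test.
4. **Profiles and gene-set enrichment.** Metagene profiles average signal
   density over scaled enhancer bodies with fixed flanks; a weighted
   Kolmogorov–Smirnov-like running-sum statistic (GSEA) with a gene-set
   permutation null asks whether a query gene set concentrates among
   genes with high enhancer signal.
5. **Screen integration.** A gene-by-cell-line dependency matrix is scored
   for lineage-selective depletion by signal-to-noise ratio (SNR) with a
   label-permutation p-value, drug IC50s are compared between lineages
   with a Mann–Whitney test, and the three screens are intersected as a
   Venn partition.

Because studies of this design typically do not deposit their raw
ChIP-seq and screen data, the package ships a first-class synthetic-data
generator (`syntheticConfig()`, `simulateDataset()`) that reproduces the
*statistical structure* of such a dataset with known ground truth, so
every stage is testable end to end.

# Key parameters

All defaults are exposed through function arguments and the pipeline
config; the important ones are:

| parameter | default | units | role |
|---|---|---|---|
| `tssExclusionBp` | 2,500 | bp | peaks whose midpoint lies within this distance of any TSS are promoter-proximal and dropped |
| `k4me3OverlapFraction` | 0.5 | fraction | overlap with a single H3K4me3 peak at or above this fraction of the peak marks it promoter-like |
| `stitchDistanceBp` | 12,500 | bp | maximum gap merged during stitching (the ROSE convention) |
| `method` (cutoff) | `tangent` | — | SE/TE cutoff rule; `top_n` and `half_signal` are alternatives |
| `windowBp` | 50,000 | bp | maximum TSS-to-enhancer distance for gene assignment (the conventional looping distance) |
| `expressionThreshold` | 1.0 | input scale | minimum expression for a gene to count as transcriptionally active |
| `minRepeats` | 2 | copies | minimum tandem GGAA copies for a microsatellite |
| `weightExponent` | 1 | — | GSEA metric weight (0 gives the classic unweighted KS form) |
| `nPermutations` | 1,000 | — | permutation count for GSEA and SNR p-values |
| seed | 17 | — | default RNG seed, recorded in all stochastic outputs |

The TSS exclusion and stitch distances follow the ROSE conventions for
this analysis family; the activity threshold of 1.0 is a pragmatic default
for FPKM-like scales, since "transcriptionally active" has no universal
definition. All of these are config-exposed precisely because they are
judgment calls.

## The super-enhancer cutoff

Three cutoff rules are provided because published SE counts are rarely
accompanied by the exact rule that produced them (a count like "the top
250 enhancers carrying more than half the signal" is consistent with more
than one rule):

* **tangent** — rescale ascending rank to $x \in [0,1]$ and signal to
  $y \in [0,1]$ and take the point minimizing $y - x$ (the point furthest
  below the diagonal, i.e. where the curve's slope passes 1). Enhancers
  with signal strictly above the cutoff signal are SUPER. This is the
  standard ROSE-style geometric rule and the pipeline default.
* **top_n** — fix the SE count directly.
* **half_signal** — the smallest top-ranked set whose summed signal first
  exceeds half the total.

Under every rule the SUPER set is a suffix of the ascending ranking; this
is asserted by the `EnhancerRanking` validity method.

# Statistical choices

* **Fisher's exact test** reports the *sample* (cross-product) odds ratio
  $(ad)/(bc)$ rather than the conditional MLE that `stats::fisher.test`
  prints, because the sample OR is a reproducible closed form; the
  two-sided p-value (sum of hypergeometric point probabilities at or
  below that of the observed table) is identical between the two. With a
  zero cell the OR is reported as `Inf`/0/`NaN` rather than smoothed.
* **Mann–Whitney** uses full labeling enumeration when
  $n_x + n_y \le 16$ with no ties (exact), otherwise the normal
  approximation with continuity and tie correction. The switch point is
  asserted in tests to cost less than 0.02 in p.
* **GSEA significance** uses *gene-set* permutation (random sets of the
  same size drawn from the ranked list): the ranking derives from a
  single sample's enhancer signal, so there are no phenotype labels to
  permute. p-values carry the $+1$ correction and can never be 0; the
  normalized ES divides by the mean |null ES| of matching sign.
* **SNR selectivity** floors each group's standard deviation at
  $\max(0.2\,|\mu_g|, 10^{-8})$, the usual signal-to-noise convention
  for expression-like data; significance comes from cell-line label
  permutation, the only null constructible from the matrix alone.
* p-values are stored at full precision; display conventions such as
  "p < 2.2e-16" are left to the caller.

## Numerical details

* Internal coordinates are 1-based closed `GRanges`; BED/bedGraph's
  0-based half-open convention is converted exactly once, at the IO
  boundary. Gap distances follow the BED convention (abutting intervals
  have distance 0).
* Enhancer ranking breaks signal ties by genomic position so ranks are
  reproducible; enhancer ids are assigned in genomic order before
  sorting by signal.
* Metagene bins divide each region body into `bodyBins` integer
  sub-intervals (the last absorbs the remainder) and report per-base
  *density*, so ~30 kb SE bodies and ~2 kb TE bodies are directly
  comparable; flank bins clipped at a chromosome start contribute zero
  over their nominal width. Regions shorter than `bodyBins` bases are
  skipped and tallied.
* Microsatellite scanning chains exact unit matches into maximal
  non-overlapping runs; reverse-complement (TTCC) runs are scanned
  separately and pooled in enrichment statistics, since EWS/FLI1 binding
  is strand-agnostic. Runs containing N break at the N. Only exact
  (uninterrupted) repeats are counted.
* The ROSE "TSS-stitching exception" (suspending stitching across three
  or more TSSs) is deliberately not implemented; with the TSS exclusion
  applied upstream it changes little at these scales, and omitting it
  keeps stitching a pure single-linkage merge. This is a documented
  divergence from ROSE.

# What the synthetic data emulates

`syntheticConfig()` defaults describe the study conditions used
throughout the test suite: 1,000 typical enhancers (log-normal lengths,
median ~2 kb) and 20 super-enhancers (median ~30 kb, built from 3–8
constituent peaks) laid out on a 4 x 8 Mb genome with at least 25 kb
between enhancers — twice the stitch distance, so stitching recovers the
planted enhancers exactly and stitching correctness is tested separately
on adversarial fixtures. Super-enhancer signal density is ~10x typical
with a Pareto tail, which reproduces the hockey-stick curve and a SUPER
signal share above one half. GGAA runs are planted at higher rates inside
super-enhancers, FLI1 peaks sit preferentially on those runs, and
FLI1-resident runs draw longer repeat counts (means ~7.3 vs ~2.3 copies).
Each SE has one target gene within 50 kb with a log-normal expression
shift; a 40-line screen plants 5 selective dependency genes (score shift
-2 SD in the 10 target-lineage lines) and a 0.2x IC50 shift.

The track is a Poisson draw per 50 bp bin of the expected RPM density
(background 0.02, enhancer strength added over constituents), which
mimics coverage granularity without simulating reads. All draws descend
from one master seed through fixed-offset sub-streams, so adding a
component never perturbs earlier draws and every output is byte-identical
under a repeated seed.

What it does **not** emulate — and what passing tests therefore do not
show about real data: mappability and GC artifacts, input-control
structure, chromatin-domain correlations, interrupted or variable-unit
microsatellites, overlapping/nested enhancers, multi-sample designs, and
screen off-target structure. Recovery statistics on this generator
validate the *computation*, not biological discovery power.

# Problem sizes in the test suite

The unit suite exercises small adversarial fixtures plus a reduced
landscape (2 x 1.5 Mb, 44 enhancers) for end-to-end runs; the acceptance
suite uses the full default conditions — 20 seeds of the 1,020-enhancer
landscape for SE and enrichment recovery, 1,000 random 10 kb sequences
for the scanner oracle, all 2x2 tables with margins up to 30 for the
Fisher oracle, 200 random gene sets for GSEA calibration, and 100 seeds
for the IC50 power check. These sizes were chosen to make the recovery
statistics stable while keeping the suite comfortably re-runnable.

# Worked example

```{r example, eval = FALSE}
library(sescreen)

## self-contained synthetic run of the whole pipeline
res <- runPipeline(list(seed = 1, simulate = TRUE), "se_run")
res$summary$n_super               # 20
res$summary$super_signal_fraction # ~0.75
res$summary$msat_odds_ratio       # ~34

## or stage by stage on your own files
peaks <- readPeaks("k27ac_peaks.bed")
track <- readSignalTrack("k27ac.bedgraph")
genes <- readGeneTable("genes.tsv")
k4    <- readPeaks("k4me3_peaks.bed")
cand  <- defineCandidates(peaks, genes, k4)
rk    <- callSuperEnhancers(quantifyEnhancers(stitchPeaks(cand), track))
summarizeRanking(rk)
```

# Known limitations

* Enhancer-gene assignment is distance-based only; no chromatin-loop
  (Hi-C) evidence is used, and nearest-gene-only assignment is not
  offered.
* Gene-level dependency scores are consumed as given (ATARiS-style
  deconvolution of shRNA reagents is out of scope), as are IC50s
  (no dose-response fitting).
* GSEA is single-set: no FDR across collections, no leading-edge
  extraction.
* bigWig tracks are not read; convert to bedGraph first.
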