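# sescreen

Super-enhancer screening and integrative dependency analysis for cancer
epigenomics, modeled on the Ewing sarcoma setting.

Ewing sarcoma carries one of the quietest mutational landscapes in cancer:
its biology is driven by the EWS/FLI1 fusion transcription factor acting
on chromatin, most visibly through **super-enhancers** — broad, stitched
clusters of H3K27Ac-marked enhancer elements that carry a disproportionate
share of total enhancer signal and mark lineage-defining genes. `sescreen`
is for computational biologists who want to run (or simulate and stress-test)
the full screening loop that turns ChIP-seq tracks and functional screens
into candidate dependencies:

1. **Call super-enhancers** — filter H3K27Ac peaks to distal candidates
   (midpoint > 2.5 kb from every TSS, not covered ≥ 50% by an H3K4me3
   peak), stitch peaks with gaps ≤ 12.5 kb, integrate RPM signal over each
   enhancer, rank ascending, and cut the hockey-stick curve. The default
   *tangent* rule rescales rank and signal to [0, 1] and takes
   `argmin(y − x)`; `top_n` and `half_signal` (smallest top set with > 50%
   of total signal) are alternatives. SUPER calls are always a suffix of
   the ranking.
2. **Assign genes** — link transcriptionally active genes (expression ≥ 1)
   to enhancers with TSS-to-boundary distance ≤ 50 kb; genes touching a
   super-enhancer are SE-associated.
3. **Quantify sequence enrichment** — scan the genome for maximal tandem
   GGAA/TTCC runs (≥ 2 copies), and test SE-vs-TE enrichment of EWS/FLI1
   peaks and microsatellites with Fisher's exact test (sample odds ratio
   `(ad)/(bc)`; two-sided hypergeometric p). Compare GGAA repeat counts
   inside vs outside FLI1 peaks with Welch's t.
4. **Profile and enrich** — metagene profiles (scaled body bins + 5 kb
   flanks, per-base RPM density) and a GSEA running-sum statistic
   (`hits add |m|^w / Σ|m|^w, misses subtract 1/(N − N_set)`) with a
   gene-set permutation null.
5. **Integrate screens** — rank lineage-selective dependencies by
   signal-to-noise ratio `(μ_t − μ_o)/(σ_t + σ_o)` with floored σ and a
   label-permutation p, compare drug IC50s between lineages
   (Mann–Whitney, exact for n ≤ 16 without ties), and intersect the three
   screens as a Venn partition.

A seeded synthetic-data generator (`simulateDataset()`) emulates the
statistical structure of such a study — hockey-stick signal landscape,
~2 kb typical vs ~30 kb super enhancers, GGAA/FLI1 enrichment at SEs,
elevated SE-gene expression, planted selective dependencies and IC50
shifts — with ground truth, so the entire pipeline is testable offline.

## Worked example

```r
library(sescreen)
res <- runPipeline(list(seed = 1, simulate = TRUE), "se_run")
```

```
[simulate] INFO generating synthetic dataset (seed 1)
[call-se] INFO 1111/1471 peaks kept as distal enhancer candidates
[call-se] INFO 1020 enhancers, 20 SUPER
[assign] INFO 3681 links; 69 SE genes
[msat] INFO 2013 microsatellite runs
[enrich] INFO GGAA repeats: mean 7.16 in FLI1 peaks vs 2.13 outside
[gsea] INFO 1 gene set(s) tested
[integrate] INFO 30 dependency hits; triple intersection size 5
```

`res$summary` (also written to `se_run/summary.json`) then holds the
headline numbers: 1,020 enhancers of which 20 are SUPER carrying 74.8% of
total signal (median lengths 2.0 kb typical vs 29.3 kb super); 69
SE-associated genes; FLI1-peak enrichment at SEs with odds ratio 23.1 and
microsatellite enrichment with odds ratio 34.1 (both p < 1e-10); GSEA of
the planted target-gene set ES = 0.95, p = 0.005; all 5 planted selective
genes in the top 10 SNR ranks; IC50 Mann–Whitney p = 3.5e-4. Every output
file is listed with an md5 digest in `se_run/manifest.json`; rerunning
with the same seed reproduces the digests byte for byte.

The same stages run on real files (`readPeaks()`, `readSignalTrack()`,
`readGeneTable()`, `scanMicrosatellites()`, `readDependencyMatrix()`, …);
see the vignette in `vignettes/super-enhancer-screening.Rmd` for the
model, parameter and design details, and `inst/scripts/sescreen.R` for a
shell entry point.

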