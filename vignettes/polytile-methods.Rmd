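---
title: "Methods: tiling-array peak calling and co-occupancy analysis with polytile"
author: "polytile authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiling-array peak calling and co-occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polytile)
```

# The analysis problem

ChIP-chip tiling arrays measure, at every ~50 bp along a genome, the log2
ratio of immunoprecipitated to input DNA. Two biological signals dominate
this package's use case in *Arabidopsis* seedlings: the binding of a
Polycomb-associated repressor (EMF1-like, narrow domains near transcription
start sites) and the repressive histone mark H3K27me3 (broad domains, often
covering whole transcription units). The pipeline turns probe-level log2
ratios into:

1. **peaks** — regions of significant enrichment;
2. **gene sets** — genes bound and/or marked, via a strand-aware search
   interval;
3. **metagene views** — TSS-aligned binned matrices, clustered High/Low;
4. **a co-occupancy classification** — bound-and-marked (EMF1_K27) genes
   split into Group I (mark lost in the repressor mutant) and Group II
   (mark retained);
5. **transcription scores and differential calls** from cDNA/genomic-DNA
   tiling arrays;
6. **category enrichment** statistics against a user-supplied annotation
   map.

# The background model and the peak caller

## Gaussian null with mirrored-negative sigma

After median-centering a track, enrichment is assumed strictly positive and
noise symmetric about zero. The negative log2 ratios are then a clean
half-sample of the null, and the null standard deviation is estimated as the
root mean square of the non-positive values:

$$\hat\sigma = \sqrt{\operatorname{mean}\{v_i^2 : v_i \le 0\}}.$$

This is the ChIPOTle-style background estimator. A `global_sd` mode (plain
standard deviation of all values) exists for comparison; on signal-rich
tracks it overestimates the null spread and costs sensitivity. Sigma is
estimated once per track, not per chromosome — one array, one noise process.
A track with no non-positive values has no estimable null and is an error.

## Window statistics

A `window_size` = 300 bp window slides in `step_size` = 50 bp steps from the
start of each chromosome to its end. A probe belongs to a window when its
center (a single base position, 0-based) lies in the half-open span
`[start, start + 300)`, so ties are impossible. For a window holding $n$
probes with mean log2 ratio $\bar v$, the one-sided p-value is the upper
tail of $\mathrm{Normal}(0, \hat\sigma/\sqrt n)$:
$p = 1 - \Phi(\bar v \sqrt n / \hat\sigma)$. All p-values are carried in
log10 space, so windows with $z \approx 40$ (p near $10^{-350}$, below
double underflow) remain ordered and reportable. Empty windows carry `NA`
and are never significant. Requiring `window_size >= step_size` guarantees
consecutive windows leave no gaps.

## Thresholds, merging, length filter

Windows with p strictly below the cutoff are selected; overlapping or
book-ended significant windows merge into one peak (span = union of the
merged windows, p = minimum window p, summit score = maximum window mean);
peaks shorter than `min_peak_length` are discarded. Two presets carry the
published parameter pairs:

| preset | p cutoff | min peak length | data type |
|--------|----------|-----------------|-----------|
| `emf1` | 1e-6     | 100 bp          | repressor binding (narrow) |
| `k27`  | 1e-35    | 300 bp          | H3K27me3 (broad, strong)   |

The cutoffs are applied to raw one-sided window p-values with no
multiple-testing correction, matching how they were published; a Bonferroni
option exists but is off by default. Windows separated by at least one
non-significant step do not merge, which is what reproduces contiguous
binding regions rather than chromosome-scale blocks.

## Calibration properties

Under the Gaussian null, the expected number of significant windows is
exactly `n_windows * alpha` by linearity, even though overlapping windows
are correlated; the test suite verifies the count lands within a factor of
two of that at a relaxed alpha = 1e-3 over 20 simulated null tracks. A full
300 bp window holds 6 probes at 50 bp spacing, so a planted domain at
$+3\sigma$ gives $z \approx 3\sqrt6 \approx 7.3$ — comfortably past the
`emf1` preset — and sensitivity for planted domains of at least 600 bp is
at least 95%.

# The synthetic-data generator

`sim_config()` / `simulate_genome()` / `simulate_chip_tracks()` /
`simulate_expression()` emulate a gapless NimbleGen-HD2-like design: probes
every 50 bp end to end, Gaussian probe noise with `noise_sd` = 0.5, genes
placed non-overlapping with at least 2 kb of intergenic space (so the
200 bp flank rule is never ambiguous). Planted features:

* **binding domains**: anchored at the TSS, extending 300–1000 bp
  downstream, at $+3\sigma$;
* **K27 domains**: from 200 bp upstream of the TSS to the TES plus up to
  500 bp of 3' extension (broad marks overrun gene ends, which exercises
  the 3'-assignment edge cases), at $+6\sigma$;
* **mutant loss**: per mutant, a configured fraction of the wild-type K27
  genes have the domain removed; each track draws independent noise;
* **expression**: per-gene, per-sample mean shifts inside gene bodies.

Two generator choices deserve explanation:

* **Genome size.** Defaults are 1,000 genes on 4 Mb. With a hard 2 kb
  intergenic gap and realistic sub-kilobase-to-2-kb gene lengths, 1,000
  genes cannot fit on 2 Mb (the gaps alone would fill it); 4 Mb leaves
  room while keeping runs fast. `simulate_genome()` refuses infeasible
  packings outright instead of silently relaxing the gap.
* **Effect sizes.** The binding effect is $+3\sigma$, detectable at
  p < 1e-6 as above. The K27 effect defaults to $+6\sigma$: the published
  K27 cutoff of 1e-35 corresponds to $z \gtrsim 12.4$, i.e. a mean window
  enrichment above $5\sigma$, so a $3\sigma$ broad mark would be invisible
  to its own preset. The very strict cutoff presupposes a strongly
  enriched mark, and the generator's default reflects that.

The generator is fully deterministic given its seed, and a Student-t noise
option (`noise_df`) is available to stress-test robustness to heavier
tails. What the simulation does **not** model: probe GC/affinity bias,
replicate-level array effects, correlated (wavy) background, partial or
heterogeneous domain loss, and sequence-level signal. Tests passing on
this generator therefore certify the statistical machinery under its
stated assumptions, not performance on any particular real array.

# Peak-to-gene assignment

The search interval of a gene runs from 200 bp upstream of the TSS to the
3' end of the transcribed region: `[tss - 200, tes)` on the plus strand,
`[tes, tss + 200)` on the minus strand, clipped at chromosome boundaries.
A peak is genic iff it overlaps the interval by at least 1 bp (the
simplest rule consistent with a "within the transcribed region" criterion;
a minimum-overlap option is available). The mapping is many-to-many by
design: a peak between two close genes can serve both, and a gene can
collect several peaks. Chromosomal densities count
peak midpoints in 100 kb half-open bins, which avoids double-counting
boundary-spanning peaks.

# Metagene matrices and High/Low clustering

For each gene, probe offsets are computed strand-relatively around the
anchor (TSS, or TES for the 3'-end-aligned variant): upstream negative,
downstream positive, minus-strand offsets negated. Offsets in
[-3 kb, +3 kb) are averaged in 100 bp bins — 60 bins per gene; bins with
no probes are missing. Bins beyond a short gene's 3' end are still filled
from the genomic track, matching how whole-genome heat maps are drawn; a
`mask_short_genes` option blanks them instead.

Clustering uses Euclidean k-means with k = 2 on the bin vectors. Three
choices the underlying publication leaves open are fixed here for
reproducibility:

* missing entries are imputed with the gene's own non-missing mean, for
  clustering only;
* the cluster with the larger mean gene-body signal (bins downstream of
  the anchor) is labeled **High** — anchoring the labels to a measurable
  quantity makes them stable across seeds and row orders;
* the stored display order is High cluster first, each cluster sorted by
  descending gene-body mean.

Degenerate inputs (all rows identical) collapse to a single cluster with a
warning, labeled by the sign of the mean gene-body signal. With exactly
two genes the 2-means split is computed directly (base k-means requires
more rows than centers).

# Co-occupancy classification

All set operations happen on gene identifiers after annotation. "Reduced
methylation" in a mutant defaults to **peak loss**: a wild-type-marked
gene is reduced iff no mutant K27 peak (same preset) overlaps its search
interval. Peak presence/absence is the only construct the pipeline defines
genome-wide, which is why it is the default; a **signal-drop** mode
(gene-body mean falling by more than a configured fraction, default 50%)
is provided as an alternative. Asking whether an unmarked gene is
"reduced" is an error, not a `FALSE` — the question is undefined.

`classify_genes()` then produces the partition: EMF1_K27 (bound and
marked) = Group I (reduced in the repressor mutant) + Group II (retained);
bound-but-unmarked genes are EMF1_no_K27; marked-but-unbound K27_only. The
identities |Group I| + |Group II| = |EMF1_K27| and |EMF1_K27| +
|EMF1_no_K27| = |bound| hold by construction and are asserted on every
synthetic run.

Set overlaps are tested with the one-sided hypergeometric upper tail
(Fisher), computed via `phyper(..., log.p = TRUE)` so p-values far below
double underflow stay representable as log10 p. The background universe is
an explicit argument and is recorded in the result: overlap p-values are
meaningless without it, and published overlap statistics are frequently
irreproducible precisely because the background was left implicit.

# Transcription scores and differential calls

Expression tracks (log2 cDNA/genomic DNA) are median-normalized; a gene's
transcription score is the mean of probe values with centers in the
strand-resolved gene body [TSS, TES). Mean aggregation keeps the score
linear in the probe values (consistent with the metagene machinery);
median aggregation is an option. For mutant-vs-wild-type calls, the
per-gene delta is thresholded at ±1.5 times the standard deviation of all
per-gene deltas: `up` above, `down` below, `unchanged` between. The
reference sd is computed at the gene level because the calls are per gene;
callers with a per-probe-derived spread can pass it via `sd_ref`. Under a
Gaussian null this flags 2(1 − Φ(1.5)) ≈ 13.4% of genes — a deliberate
property of the published rule, verified by simulation in the test suite.
Identical samples give sd = 0, which is reported as all-unchanged with a
warning rather than an error.

# Category enrichment

The annotation is a flat gene-to-category multimap (no ontology
propagation). Per category, the observed group count is tested against
`lambda = group_size * genome_fraction` with a Poisson upper tail, except
when the expected count falls below 5, where the Poisson approximation is
weakest and Fisher's exact test is used instead — a concrete rendering of
the published "Poisson for categories, Fisher for small gene numbers"
split; the threshold is configurable. Raw p-values are reported (the
published tables are raw), with a Benjamini–Hochberg column added for
convenience.

# Pipeline, determinism and problem sizes

`run_pipeline()` executes simulate/ingest → call peaks → annotate →
metagene/cluster → classify → score/DE → enrich, writing every stage's
artifacts (bedGraph, BED6+1, TSV, JSON report) under one output
directory. All randomness derives from the single config seed through
per-stage hashed seeds, so identical config + seed reproduces identical
artifacts byte for byte; the report's wall-clock field is the one value
kept out of the on-disk report for that reason. A failing stage leaves
completed artifacts and a report naming the failed stage, then propagates
the error.

The test suite and the acceptance script run on simulated genomes of 0.4–8
Mb with 40–2,000 genes — sizes chosen so each statistical property is
measured with sampling noise well inside its stated tolerance while a full
run completes in about a minute. Fraction-recovery checks (e.g. planted
loss fractions 0.57/0.84 within ±0.03) average 10 independent seeds at
~400+ marked genes per seed.

# Known limitations

* The 3'-end-aligned ("end analysis") metagene is a stated approximation:
  it reuses the TSS machinery anchored at the TES, without gene-length
  normalization or weighting schemes that dedicated end-analysis methods
  apply.
* Replicate hybridizations are handled only by per-probe mean combination
  (`combine_tracks()`); there is no replicate variance model or
  irreproducibility analysis.
* Normalization is median centering only — no quantile normalization,
  probe-level background correction, or GC correction.
* The peak caller's type-I guarantees are proved under the symmetric-noise
  assumption the generator shares; heavy-tailed or asymmetric real-array
  noise will inflate the effective false-positive rate at a fixed cutoff.
* `reduced_methylation()`'s peak-loss criterion is binary and
  threshold-coupled: a gene whose mutant domain weakens just past the
  cutoff counts as a full loss. The signal-drop mode trades that edge for
  a tunable continuous criterion.
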