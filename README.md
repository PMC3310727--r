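# polytile

Genome-wide ChIP-chip tiling-array analysis of Polycomb-type repression:
peak calling for a TSS-proximal repressor (EMF1-like binding) and for the
broad repressive histone mark H3K27me3, peak-to-gene assignment,
TSS-aligned metagene clustering, co-occupancy classification of genes
(Group I/II), tiling-array transcription scores with differential calls,
and category-enrichment statistics. A synthetic tiling-array generator
with planted ground truth makes the whole pipeline testable end to end
without any external download.

**Who it is for:** epigenomics / regulatory-genomics analysts working with
probe-level log2-ratio tracks (bedGraph or WIG) from dense tiling arrays,
who need a reproducible route from probe signal to gene-level biology.

## The statistics at the core

* **Peak calling.** A 300 bp window slides in 50 bp steps. After median
  centering, the background sigma is estimated from the mirrored negative
  log2 ratios, `sigma = sqrt(mean(v^2 | v <= 0))`; each window's mean is
  tested one-sided against Normal(0, sigma/sqrt(n)). Significant windows
  (binding preset p < 1e-6, min length 100 bp; H3K27me3 preset p < 1e-35,
  min length 300 bp) merge into peaks; p-values live in log10 space so
  extreme enrichment never underflows.
* **Gene assignment.** A peak belongs to a gene when it overlaps the
  strand-aware interval from 200 bp upstream of the TSS to the 3' end.
* **Metagene clustering.** Average signal per 100 bp bin across ±3 kb of
  the TSS, k-means with k = 2, clusters labeled High/Low by gene-body
  signal.
* **Co-occupancy.** EMF1_K27 = bound ∩ marked; Group I lost the mark in
  the repressor mutant, Group II retained it. Overlaps are scored with the
  one-sided hypergeometric (Fisher) tail against an explicit universe.
* **Expression.** Per-gene mean of median-normalized log2(cDNA/gDNA)
  probes; mutant − WT deltas thresholded at ±1.5 sd.
* **Enrichment.** Poisson upper tail at `lambda = group_size *
  genome_fraction`, switching to Fisher's exact test for small expected
  counts.

See `vignettes/polytile-methods.Rmd` for assumptions, parameter meanings
and design choices.

## Worked example

Simulate a 1 Mb mini-genome with 200 genes where 58% of repressor-bound
genes are also K27-marked and 57% of marked genes lose the mark in the
repressor mutant; then run the core steps:

```r
library(polytile)
cfg <- sim_config(genome_length = 1e6, n_chromosomes = 1, n_genes = 200,
                  co_occupancy = 0.58, mutant_loss = c(emf1 = 0.57),
                  seed = 42)
genome <- simulate_genome(cfg)
chip   <- simulate_chip_tracks(genome, cfg)

emf1_peaks <- call_peaks(chip$tracks$emf1,   caller_params("emf1"),
                         genome$chrom_sizes)
k27_wt     <- call_peaks(chip$tracks$k27_WT, caller_params("k27"),
                         genome$chrom_sizes)
k27_emf1   <- call_peaks(chip$tracks$k27_emf1, caller_params("k27"),
                         genome$chrom_sizes)

bound   <- assign_peaks_to_genes(emf1_peaks, genome$genes,
                                 chrom_sizes = genome$chrom_sizes)$bound_genes
marked  <- assign_peaks_to_genes(k27_wt, genome$genes,
                                 chrom_sizes = genome$chrom_sizes)$bound_genes
reduced <- reduced_methylation(k27_wt, k27_emf1, genome$genes,
                               chrom_sizes = genome$chrom_sizes)
status  <- classify_genes(bound, marked, names(reduced)[reduced],
                          genome$genes$gene_id)
table(status$group)
fisher_overlap(bound, marked, genome$genes$gene_id)
```

Output:

```
emf1 peaks: 100 (sigma = 0.513)
K27 WT peaks: 115, K27 emf1 peaks: 35

 EMF1_K27_groupI EMF1_K27_groupII      EMF1_no_K27         K27_only
              36               22               42               22
            none
              78

overlap 58 vs 40.0 expected; log10 p = -6.8
```

Reading it: all 100 planted binding domains were recovered (sigma was
estimated at 0.513 against a true 0.5); 58 of the 100 bound genes are also
K27-marked — exactly the planted 58%, and far above the 40 expected under
independence (log10 p = −6.8). Of those 58 EMF1_K27 genes, 36 (62%) lost
the mark in the mutant (Group I) against a planted 57% — the deviation is
binomial noise at n = 58; the acceptance script measures the same fraction
at n ≈ 580 and lands within a point or two.

The same analysis runs from one config via `run_pipeline()` (or the
`exec/polytile` command line), which writes peaks (BED6+1), densities and
tracks (bedGraph), the per-gene status table (TSV) and a JSON run report.

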