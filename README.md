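# conecod

Photoreceptor population analysis for NRL-null retinal organoid single-cell
transcriptomics.

NRL commits photoreceptor precursors to the rod fate. In NRL-null retinal
tissue, would-be rods adopt a hybrid rod/cone identity — **cods** — with very
high S-opsin (*OPN1SW*), cone genes expressed at rod-typical levels and rod
genes at cone-typical levels. `conecod` implements the single-cell analysis
used to characterize these populations as a reusable, tested R package:

* **QC & normalization** — cell filters (< 200 detected genes; > 20% (d170)
  or 15% (d100) mitochondrial UMIs), gene filter (detected in < 2 cells),
  counts-per-10k natural-log normalization, binned-dispersion HVG selection.
* **Populations** — PCA/k-means partitioning, marker-panel annotation,
  expression-group statistics (% expressing, mean within expressers, mean
  total), Spearman mapping onto reference profiles, 2^−ΔΔCq qPCR folds with
  Mann–Whitney p-values.
* **Differential expression** — per-population WT-vs-mutant Wilcoxon
  rank-sum (exact ≤ 12 samples, tie/continuity-corrected approximation
  otherwise), average natural-log fold change with the 0.5 (~1.6-fold)
  threshold, Bonferroni correction over genes expressed at the timepoint,
  and a three-way classifier placing cod cells against WT rods and cones
  (rod-level / cone-level / intermediate / above-both / below-both).
* **Gene-set enrichment** — Monte-Carlo resampling null for
  binding-site target sets with a closed-form expectation and an exact
  hypergeometric co-report; generic ORA for user gene sets.
* **Pseudotime** — semi-supervised NB likelihood-ratio ordering-gene
  selection (top 780 non-ribosomal/mitochondrial), centroid-MST pseudotime
  with one rod/cone bifurcation, NB branch-node DE.
* **Synthetic data** — an NB UMI simulator (depth, mitochondrial-fraction
  and composition covariates, bifurcating maturation axis) with full ground
  truth, so every stage is testable offline.

The core enrichment statistic, for a target set *S* (|S| = 475 genes with
MEF2C binding sites, of which |S∩U| lie in the background universe *U* of
expressed genes), draws *k* genes from *U* without replacement and compares
the observed overlap fraction |S∩selection|/|S| to the resampled null; the
closed-form expectation is |S∩U|·k/(N·|S|).

## Worked example

Simulate a two-genotype organoid dataset, run the full pipeline, and test the
binding-site enrichment at the sizes of the published experiment:

```r
library(conecod)

cfg <- run_config(
  spec = synthetic_spec(n_cells_per_genotype = 1500, baseline_mean = 1,
                        n_genes_total = 800),
  qc = qc_config(min_genes_per_cell = 50),
  n_hvg = 400, seed = 42)
report <- run_pipeline(cfg)
report
#> conecod run report (config d0998a23ce13)
#>   input      cells=3000, genes=800
#>   post_qc    cells=2707, genes=800
#>   clustered  cells=2707, clusters=12
#>   DE comparisons: amacrine (0 sig), bipolar (0 sig), developing (0 sig),
#>     horizontal (1 sig), ML_cone (0 sig), muller (1 sig), RGC (0 sig),
#>     rod (4 sig), S_cone (2 sig)
#>   cod classes: cone-level=4, rod-level=1
#>   enrichment (expressed): 100.0% observed vs 100.0% null
#>   wall time: 20.5 s
```

The QC stage removed 293 low-complexity/high-mitochondrial cells; the "rod"
comparison (WT rods vs mutant rod-like cells) finds the silenced rod program,
and the cod classification table places cone genes at rod level and vice
versa. (At this demo scale every simulated gene is expressed, so the
expressed-gene enrichment is trivially 100% — informative numbers come from
the published sizes below.)

```r
universe   <- c(sprintf("TGT%05d", 1:375), sprintf("BG%05d", 1:14282)) # 14,657 expressed genes
target_set <- c(sprintf("TGT%05d", 1:375), sprintf("OUT%05d", 1:100))  # 475, 375 in universe
de_genes   <- c(sprintf("TGT%05d", 1:34),  sprintf("BG%05d", 1:757))   # 791 DE genes, 34 targets

enrichment_test(universe, target_set, de_genes, n_iterations = 1000, seed = 1)
#> Gene-set resampling enrichment (N=14657, |S|=475, |S in U|=375, k=791)
#>   observed: 34 genes (7.2%)   expected: 4.3% (closed form)
#>   null mean over 1000 iterations: 4.26% (sd 0.94%)
#>   p (t) = 1e-300   p (empirical) = 0.00999   p (hypergeometric) = 0.00215
```

34 of the 475 binding-site genes among 791 differentially expressed genes is
7.2%, against a resampling expectation of 4.26% — a significant enrichment by
all three read-outs. `tidy()`/`glance()` methods and `autoplot()` are
available for enrichment, trajectory and run-report objects.

A thin CLI wrapper ships at `inst/cli/conecod.R`
(`simulate | qc | enrich | run`).

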