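# filamix

Mixture deconvolution and degradation diagnostics for two-cell-type
filament transcriptomes.

## The problem

Heterocyst-forming cyanobacteria grow as filaments containing two cell
types: photosynthetic vegetative cells and N₂-fixing heterocysts (roughly
5–10% of cells). Transcriptome experiments on these organisms typically
measure three sample types per growth condition — whole filaments (F),
isolated vegetative cells (V) and isolated heterocysts (Ht) — in
biological triplicate. Two statistical questions follow directly from the
design:

1. **Composition.** Whole-filament RNA is a mixture. For each gene *i*
   the replicate-mean signals should obey the no-intercept linear model

   F*ᵢ* = *a* V*ᵢ* + *b* Ht*ᵢ*

   with global coefficients *a*, *b* reflecting the relative RNA
   contributions of the two cell types (expected near 0.92 and 0.08).

2. **Isolation artifacts.** Cell isolation takes hours, and some
   transcripts — classically the nitrogenase (*nif*) cluster, which is
   heterocyst-specific and abundant — are degraded during it. Such genes
   betray themselves by violating the mixing model: the filament carries
   the intact signal while the isolated fraction does not. The package
   ranks genes by the weighted residual

   *rᵢ* = (F*ᵢ* − *a*V*ᵢ* − *b*Ht*ᵢ*) / ‖(V*ᵢ*, Ht*ᵢ*, F*ᵢ*)‖

   — the distance from the model plane as a proportion of the gene's
   overall transcript level. Large positive *rᵢ* (F ≫ *a*V + *b*Ht) is
   the degradation signature.

Around this core the package provides the full analysis pipeline:
TSV/GEO-series-matrix ingestion, quantile normalization and pairwise
replicate R²/Spearman QC, low-signal/high-variability data reduction,
OLS/grid-search/orthogonal estimators with gene-level bootstrap intervals,
Welch-test volcano classification (>2-fold, p < 0.01), sample PCA,
functional-category transcript-share profiles, the seven-level
signal-intensity bin scale, RT-qPCR standard-curve relative
quantification, and cell-specificity estimation for the RNA preparations.
A synthetic-data generator (`simulate_dataset()`) produces complete
experiments with known ground truth — latent cell-type profiles, planted
differential expression, planted heterocyst-specific degradation — for
validating every step.

## Worked example

```r
library(filamix)

sim <- simulate_dataset(sim_params(n_genes = 4000, noise_cv = 0.1,
                                   degraded_gene_count = 10,
                                   degradation_factor = 0.1, seed = 42))
em <- sim$matrix
#> ExpressionMatrix: 4000 genes x 9 samples
#> conditions: P | sample types: F V Ht

red <- reduce_dataset(em, "P")
red$report
#>   condition genes_in genes_removed_low_signal genes_removed_variability
#> 1         P     4000                      461                         0
#>   genes_out mean_floor cv_threshold
#> 1      3539        128          0.5

m   <- condition_means(red$matrix, "P")
fit <- fit_mixture(m$v_mean, m$ht_mean, m$f_mean, method = "tls",
                   n_boot = 500, seed = 1)
fit
#> MixtureFit (tls): a = 0.9163, b = 0.0843, sse = 8.768, n = 3539
#>   bootstrap 95% CI (n_boot = 500): a [0.9094, 0.9230], b [0.0781, 0.0900]
```

The simulation was built with *a* = 0.92, *b* = 0.08; both intervals cover
the truth. Genes degraded in isolated heterocysts surface as the top
positive outliers:

```r
wr  <- weighted_residuals(fit, m$v_mean, m$ht_mean, m$f_mean,
                          gene_ids = m$gene_id)
top <- rank_outliers(wr, 12, "f_high")
head(top[, c("gene_id", "f_mean", "v_mean", "ht_mean", "f_calc", "r")], 4)
#>      gene_id f_mean v_mean ht_mean f_calc     r
#> 1  gene_2597   1197    515     803    539 0.430
#> 2  gene_0680   1486    678     941    701 0.417
#> 3  gene_1944    371    166     251    174 0.413
#> 4  gene_0071    312    147     215    153 0.391

sum(sim$truth$degraded_genes %in% top$gene_id)
#> [1] 8
```

Eight of the ten planted degraded genes rank in the top 12 here; the
remaining two fell below the 128-SIU low-signal floor *because of* the
degradation and were removed by `reduce_dataset()` — running the detector
on the unreduced matrix recovers all ten. Differential expression and the
qPCR controls:

```r
de <- de_table(red$matrix, "P")
de$counts
#> up_in_Ht  up_in_V
#>      181      190

curve <- fit_standard_curve(c(1, 10, 100), c(30, 26.678, 23.356))
curve
#> StandardCurve: Ct = 30.0000 + -3.3220 * log10(amount), R2 = 1.0000, efficiency = 100.0%

estimate_specificity(1, 0.069)$specificity_percent
#> [1] 93.1
```

The counts are the genes classified up in each cell type at >2-fold and
p < 0.01 (Welch test on log2 signals); the specificity call says that a
vegetative-cell marker showing 6.9% relative cross signal in a heterocyst
RNA preparation implies that preparation is 93.1% cell-specific.

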