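# lncscape

Integrative analysis of long non-coding RNA (lncRNA) expression in breast
cancer cohorts, implemented as a tested R package plus a numbered analysis
workflow. The package targets the recurring question of bulk tumor
transcriptomics: when a lncRNA's expression tracks a clinical subtype, is
that signal coming from the cancer cells themselves or from the cellular
composition of the tumor microenvironment — and which regulatory elements
drive it?

The pipeline runs end to end on synthetic two-cohort data with planted
ground truth, so every stage is scored against a known answer. Real
genes × samples TPM matrices, clinical tables, BED/BEDPE tracks and beta
matrices can be substituted through the same readers.

## What the pipeline computes

1. **Expression preparation** — genes kept when expressed > 1 TPM in > 5 %
   of samples with IQR(log2(TPM+1)) > 0.1; sample clustering on correlation
   distance (1 − r) with Ward.D2 linkage.
2. **Differential expression** — per cohort, a two-group moderated *t*:
   ordinary per-gene fits with empirical-Bayes variance shrinkage
   s̃²_g = (d₀s₀² + df·s²_g)/(d₀ + df), hyperparameters (d₀, s₀²) estimated
   by the method of moments on log s²_g (solved through the trigamma
   inverse), p-values on df + d₀ degrees of freedom, BH adjustment. A gene
   replicates when adjusted p < 0.05 in both cohorts with the same logFC
   sign.
3. **Survival screening** — univariate Cox proportional hazards per lncRNA
   (Newton–Raphson on the Breslow partial likelihood), run separately
   within ER strata, BH-adjusted per stratum.
4. **Co-expression biclustering** — Spearman ρ of every lncRNA against
   every mRNA in both cohorts; edges kept under Bonferroni control
   (p·m < 0.05 in both cohorts, matching sign); genes kept when their
   degree exceeds the mean degree; edges kept when |ρ| > 0.4 in both
   cohorts; the surviving relation matrix binarized to ±1 and biclustered
   (average linkage on 1 − r) into 3 lncRNA × 3 mRNA clusters.
5. **Cell-type attribution** — each lncRNA modeled as
   `expr ~ ESR1 + fibroblast score + lymphocyte score` with standardized
   predictors; the best-explaining variable is the smallest coefficient
   p-value; Kruskal–Wallis compares coefficients across clusters;
   single-cell negative-binomial counts verify the assignment
   (log-normalization with scale factor 10 000, dot-plot summaries,
   one-vs-rest Wilcoxon markers).
6. **Promoter characterization** — strand-aware −200/+100 windows around
   each lncRNA TSS; promoters overlapping padded protein-coding loci
   flagged; nearest-gene assignment; ER⁺ vs ER⁻ ATAC accessibility at
   promoter-containing peaks (Wilcoxon); chromHMM-state enrichment
   (hypergeometric, all lncRNA promoters as background, states with < 10
   supporting promoters excluded) and per-set TFBS enrichment (one-sided
   Fisher exact).
7. **Cis methylation** — CpG beta matrices preprocessed (≤ 50 % missing,
   kNN imputation with k = 10, IQR > 0.1); same-chromosome CpG–lncRNA
   Spearman correlations, Bonferroni-corrected over the number of pairs
   actually tested, kept when inverse and replicated in both cohorts;
   kept CpGs characterized by chromatin state and accessibility; a pair is
   loop-validated when the CpG and the target TSS fall in two different
   feet of the same ChIA-PET loop.

All exact small-sample statistics (hypergeometric, Fisher, Wilcoxon,
Kruskal–Wallis, BH/Bonferroni) are exposed in one module and checked
against exhaustive enumeration in the test suite.

## Worked example

```r
library(lncscape)
res <- run_all(sim_config(seed = 1))
self_check(res)[c("ari_lnc", "attribution_frac", "cis_precision", "cis_recall")]
```

On the default study conditions (two cohorts × 300 samples, 600 lncRNAs
with planted clusters of 120/60/40, 2000 mRNAs, 50 enhancer CpG–lncRNA
pairs among 5000 decoys) this prints:

```
$ari_lnc
[1] 1

$attribution_frac
1 2 3
1 1 1

$cis_precision
[1] 1

$cis_recall
[1] 1
```

i.e. the biclustering recovers the planted lncRNA clusters exactly
(adjusted Rand index 1), every cluster attributes to its planted driver
(ESR1 / fibroblast / lymphocyte), and the 50 planted enhancer pairs are
recovered from ~700 000 same-chromosome tests without false positives.

The numbered drivers under `analysis/` run the same stages file-by-file
and narrate their findings; from the repository root:

```sh
Rscript analysis/01_simulate.R          # writes results/data/
Rscript analysis/02_prep.R              # 2600 genes -> 2584 -> 2568
Rscript analysis/03_differential_expression.R   # 230 replicated, r = 0.97
Rscript analysis/04_coexpression.R      # 1 136 000 pairs, ARI = 1.000
Rscript analysis/05_attribution.R
Rscript analysis/06_promoters.R
Rscript analysis/07_methylation.R       # precision 1.000, recall 1.000
```

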