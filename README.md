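# ferroscore

Ferroptosis gene-signature scoring for T cell-mediated rejection (TCMR)
after kidney transplantation.

Biopsy-proven TCMR is a major threat to early allograft survival, and
pathology remains the diagnostic bottleneck. `ferroscore` implements a
transcriptomic pipeline that classifies transplant samples by the
expression activity of a ferroptosis gene panel (drivers, suppressors and
markers of iron-dependent, lipid-peroxidation cell death) and turns it
into a single per-sample score usable for diagnosis and for graft-loss
prognosis:

1. **Consensus clustering** of samples over the panel subspace
   (subsampled resampling, average linkage on 1 − Pearson correlation),
   with quantitative selection of the number of clusters by PAC
   (proportion of ambiguous clustering) or CDF Δ-area.
2. **Moderated differential expression** between the two clusters
   (empirical-Bayes variance shrinkage, BH-adjusted p < 0.05 and
   |log2 FC| > 0.5) giving an up signature *A* and a down signature *B*.
3. **PCA scoring**: per signature, genes are centered at training means
   and reduced to their first principal-component coordinate; the score is

   `ferroptosis score = PC1_B − PC1_A`

   (oriented so cases score higher), and external cohorts are projected
   through the *stored* rotation — no refitting.
4. **Evaluation**: ROC/AUC (exact Mann–Whitney), Youden cutoff,
   Welch t comparisons, Kaplan–Meier curves, log-rank test and a
   fixed-horizon (3-year) survival ROC.

A synthetic-cohort generator with planted driver/suppressor shifts and
score-linked survival makes the whole pipeline testable offline; readers
for TSV/GCT expression, CSV phenotypes, TSV gene panels and a JSON model
format support real cohorts supplied by the user.

## Worked example

```r
library(ferroscore)

res <- run_pipeline(list(seed = 7, simulate = list()))
res$consensus
#> Consensus clustering result
#>   samples: 80  resamples: 200  fraction: 0.80  base: hclust/pearson
#>   k range: 2, 3, 4, 5, 6, 7, 8, 9
#>   PAC: k=2 0.000  k=3 0.034  k=4 0.056  k=5 0.085  k=6 0.110  k=7 0.124  k=8 0.132  k=9 0.128
#>   chosen k: 2  (cluster sizes: 40, 40)
res$signatures
#> Signature pair (|logFC| > 0.5, FDR < 0.05)
#>   A (up in case cluster):   30 genes
#>   B (down in case cluster): 30 genes
res$reports$training$roc
#> ROC: AUC = 1.000 (n+ = 40, n- = 40)
#> Youden cutoff 3.764: sensitivity 1.000, specificity 1.000
```

The default synthetic study (80 samples, 150-gene panel, half of the
drivers up-shifted and half of the suppressors down-shifted by 1 log2
unit in cases) is cleanly separable, so the clustering picks k = 2 with
zero ambiguity (PAC = 0), the signatures recover exactly the 30 + 30
planted genes, and the training ROC is perfect. Projection onto a new
cohort reuses the stored rotations:

```r
held <- generate_cohort(cohort_config(seed = 9901))
sc <- project_scores(res$model, held$expression)
roc_auc(sc$ferroptosis_score, held$phenotypes$diagnosis, positive = "TCMR")$auc
#> [1] 1
```

Prognosis on a simulated survival cohort (hazard doubling per SD of the
latent score) uses the same score:

```r
res$reports$training$survival$logrank_p     # 6.9e-05: high scorers fail faster
res$reports$training$survival$horizon_roc   # 3-year graft-loss ROC
```

See `vignettes/ferroscore-methods.Rmd` for the model, its assumptions,
all tunable parameters, and what the synthetic generator does and does
not emulate.

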