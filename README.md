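# scganchor

Anchor-gene co-expression discovery and signature scoring for single-cell
and bulk transcriptomes.

## The problem

A single gene's expression is an unreliable readout in single-cell RNA-seq:
dropout turns truly expressed transcripts into zeros, and in bulk tumor
tissue the malignant-cell signal of a gene is diluted by stroma and immune
infiltrate. `scganchor` addresses both problems for a chosen *anchor gene*
(a gene whose cellular program you want to track — a channel subunit, a
transcription factor, a drug target) by replacing the gene with the program
co-expressed with it:

1. **Co-expression discovery.** In annotated single-cell data, every gene is
   regressed against the anchor within each cell type using a Tweedie
   exponential-dispersion GLM (log link, variance `V(mu) = mu^p` with
   `p = 1.1` by default) — a family built for nonnegative responses with
   exact zeros, i.e. dropout-ridden log-expression. For malignant cells the
   model is fitted per patient and the coefficients are pooled by
   inverse-variance fixed-effect meta-analysis
   (`beta_pool = sum(w_i b_i) / sum(w_i)`, `w_i = 1/se_i^2`). Genes with
   `beta > 0` and BH FDR `< 0.05` are the anchor-coexpressed genes (SCGs);
   the top 100 by p-value form the signature.
2. **Signature scoring.** In single cells, each signature gene is
   centralized against the mean of 100 control genes drawn from the same
   pooled-expression bin (25 bins), and the per-cell score is the mean of
   the centralized values — robust to per-cell library quality. In bulk,
   the score is the plain mean of the signature genes.
3. **Downstream stages.** A modified jackstraw permutation test associates
   every bulk gene with the Z-scored signature (pooled null from
   independently permuted genes, add-one p-values); a minimum-hypergeometric
   (mHG) test with an exact dynamic-programming p-value checks signature
   enrichment in externally ranked lists; hypergeometric ORA scores gene-set
   collections; marker-based metagenes quantify microenvironment cell types;
   ligand–receptor tables are mapped to crosstalk edges; and Cox,
   logistic, and rank/permutation tests relate scores to survival and
   treatment response.

Supporting modules handle QC (pooled-expression filtering
`E_pooled = log2(mean TPM + 1) >= 3`, duplicate-gene handling, symbol
correction, T-cell subtype classification from CD8A/CD8B, FOXP3/IL2RA and
CD4 thresholds), housekeeping-gene detection curves that turn dropouts into
per-entry reliability weights, and a synthetic-data generator that emulates
the whole setting (multi-patient cohorts, planted co-expression modules,
magnitude-dependent dropout, bulk mixtures with tumor purity, survival
outcomes) with ground truth for validation.

## Worked example

Simulate the default cohort (8 patients × 150 malignant cells plus
microenvironment, 2,000 genes, a planted 100-gene anchor module), discover
malignant SCGs, project the signature into bulk mixtures, and test the
survival association:

```r
library(scganchor)

cfg <- sim_config(seed = 11)
sim <- simulate_single_cell(cfg)

stats <- sim$expr |>
  filter_genes(anchor = "ANCHOR") |>
  discover_scgs(sim$annotation, "ANCHOR", "malignant")
scg <- select_scgs(stats, top_n = 100)
scg
#> <scg_set> 100 anchor-coexpressed genes (malignant cells)
#> # A tibble: 100 x 9
#>   gene_id cell_type      fdr  beta     se     z        p k_studies  rank
#> 1 MOD033  malignant 2.31e-17 0.250 0.0269  9.30 1.39e-20         8     1
#> 2 MOD007  malignant 2.31e-17 0.282 0.0306  9.24 2.40e-20         8     2
#> 3 MOD036  malignant 2.31e-17 0.277 0.0301  9.20 3.59e-20         8     3
```

Each row is one signature gene: the meta-analyzed Tweedie coefficient
(`beta`, per log2 unit of the gene), its pooled standard error, Wald `z`,
p-value, BH FDR, and the number of patients pooled (`k_studies`). 98 of the
100 selected genes here are planted module members.

```r
bulk <- simulate_bulk(cfg, sim)
bs <- score_bulk(bulk$expr, scg)

cl <- bulk$clinical
cl$score <- bs$score
cox_fit(cl, covariates = c("gender", "age"))
#> <anchor_cox> n = 150, events = 105, ties = efron
#>   term      log_hr     se    hr conf.low conf.high         p
#> 1 score   -0.375   0.0944 0.688    0.571     0.827 0.0000716
#> 2 genderM  0.112   0.202  1.12     0.753     1.66  0.581
#> 3 age      0.00856 0.0102 1.01     0.989     1.03  0.400
```

The hazard ratio is per standard deviation of the bulk score; the planted
effect (log-HR −0.3 per SD, HR 0.74) sits inside the confidence interval.
The bulk score tracks the true malignant fraction at Spearman ρ = 0.99.
`autoplot()` methods exist for scores, jackstraw results, metagene
correlations and mHG profiles; fitted objects support `tidy()`/`glance()`.

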