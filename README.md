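# cordsig

Cross-cohort discovery and replication of perinatal asthma-risk gene
expression signatures in cord blood.

## The problem

Perinatal risk factors for childhood asthma — male sex, preterm birth, low
birthweight and maternal obesity — leave transcriptional traces in cord
blood mononuclear cells (CBMCs). Public cord-blood microarray datasets are
individually small and each records only some of these covariates, so no
single study can characterise the shared signature. `cordsig` implements a
pipeline that:

1. estimates, within each dataset, a standardized per-gene effect for every
   available covariate (Hedges' *g* for newborn sex; Fisher-*z* correlation
   for gestational age, birthweight and maternal pre-pregnancy BMI);
2. combines the per-study effects gene-by-gene with inverse-variance
   **DerSimonian–Laird random-effects meta-analysis**, controlling FDR by
   Benjamini–Hochberg;
3. pools the four covariate z-score vectors into one risk-oriented score,

   ```
   z_pooled = ((z_male + z_ppbmi) - (z_ga + z_bw)) / 4
   ```

   with missing components imputed as zero (the denominator stays 4);
4. uses `z_pooled` as a pre-ranked list for **weighted Kolmogorov–Smirnov
   gene-set enrichment** with gene-label permutation p-values;
5. replicates the signature in an independent RNA-seq cohort: per-gene
   negative-binomial models of counts against the number of perinatal risk
   factors (gestational age < 37 weeks, birthweight < 3000 g, maternal
   pre-pregnancy BMI > 30, male — strict inequalities) give a Wald
   `z_rnaseq`, and the **replication score** `RS = z_pooled * z_rnaseq`
   selects concordant genes at `RS > 3`;
6. summarises replicating genes as a first-principal-component signature
   per subject, oriented so positive scores mean increased expression of
   low-risk genes, and correlates it with the risk-factor count;
7. associates standardized cord-serum proteins with asthma and FEV1/FVC
   outcomes under four covariate-adjustment models, with LMG
   relative-importance and McFadden pseudo-R² drop-one decompositions.

Every stage has a matching simulator with planted ground truth
(`sim_config()`, `simulate_microarray_collection()`,
`simulate_rnaseq_cohort()`, `simulate_outcome_cohort()`), so recovery,
calibration and determinism are testable end to end.

## Worked example

Six fully-observed simulated datasets, 500 genes with 20 planted signal
genes, then the whole pipeline:

```r
library(cordsig)
cfg <- sim_config(n_datasets = 6, dataset_sizes = c(40, 60, 50, 45, 80, 64),
                  availability_mask = rep(list(c("sex","ga","bw","ppbmi")), 6),
                  n_genes = 500, n_signal_genes = 20, seed = 2026)
res <- run_signature_pipeline(cfg)
head(res$replication[order(-res$replication$rs), ], 5)
#>    gene z_pooled z_rnaseq   rs passes
#>  g00349    -7.95    -9.97 79.3   TRUE
#>  g00045     7.58     8.81 66.7   TRUE
#>  g00110    -8.71    -7.02 61.1   TRUE
#>  g00347    -7.62    -7.30 55.7   TRUE
#>  g00403    -8.03    -6.93 55.6   TRUE
sum(res$replication$passes)
#> 20
res$risk_correlation
#> R = -0.98 [-0.99, -0.96], p = 9.6e-22
```

All 20 replication-score passers are planted genes; negative `z_pooled`
marks low-risk genes (expression falls with accumulating risk factors), and
the per-subject signature eigenvalue declines almost linearly with the
risk-factor count. The outcome arm recovers a planted protective protein
association (true OR 0.5 per SD):

```r
coh <- simulate_outcome_cohort(cfg)
coh$pglyrp1_z <- standardize_protein(coh$pglyrp1)
fit_outcome_model(coh, "current_asthma_mid", "pglyrp1_z", "model3")
#>             outcome predictor  model   family estimate    lo    hi        p   n
#>  current_asthma_mid pglyrp1_z model3 logistic    0.509 0.376 0.688 1.17e-05 347
```

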