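---
title: "Methods: cross-cohort discovery of perinatal asthma-risk gene signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-cohort discovery of perinatal asthma-risk gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cordsig` chains six stages: simulation with planted truth, per-gene
random-effects meta-analysis, risk-score pooling, pre-ranked set
enrichment, RNA-seq replication, and serum-protein outcome models. This
vignette records the statistical model of each stage, the tunable
parameters, the numerical conventions, and the design choices that were
genuinely open.

## 1. Study-level effects and random-effects meta-analysis

Within one dataset, the association of a gene's log2 expression with a
perinatal covariate is summarised as a standardized, inverse-variance-
combinable effect:

* **Newborn sex** (binary, 1 = male): Hedges' small-sample-corrected
  standardized mean difference,
  $g = J\,(\bar x_1 - \bar x_0)/s_p$ with $J = 1 - 3/(4\,\mathrm{df} - 1)$
  and variance $\frac{n_1+n_0}{n_1 n_0} + \frac{g^2}{2(n_1+n_0)}$.
* **Gestational age (weeks), birthweight (g), maternal pre-pregnancy BMI
  (ordinal 0–3: <18.5 / 18.5–25 / 25–30 / ≥30)**: Pearson correlation
  mapped to Fisher's $z = \operatorname{atanh}(r)$, variance $1/(n-3)$.
  The ordinal BMI coding is treated as numeric 0–3 exactly as defined.

The choice of two effect families was open: inverse-variance random-effects
machinery is classically described for two-class comparisons, and nothing
in the analysis being emulated fixes how continuous covariates entered.
Hedges' *g* for the binary covariate and Fisher-*z* for the continuous and
ordinal ones are both dimensionless, approximately normal with known
variance, and poolable on a common scale; this is the package's documented
convention. Datasets with fewer than 4 samples, a single-sex sample, or a
constant covariate cannot contribute ("insufficient data").

Per gene, study effects $e_i$ with variances $v_i$ are combined by the
DerSimonian–Laird moment estimator: fixed weights $w_i = 1/v_i$ give
$Q = \sum w_i (e_i - \hat e_{FE})^2$ and
$\hat\tau^2 = \max\!\big(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w)\big)$;
random weights $w^*_i = 1/(v_i + \hat\tau^2)$ give the combined effect,
its SE, $z = \mu/se$ and a two-sided normal p-value. When $Q \le k-1$ the
estimate reduces exactly to the fixed-effect combination. Genes observed in
a single dataset pass through flagged (`single_study`) rather than being
dropped, because the pooled score tolerates missing components; they are
excluded from the Benjamini–Hochberg adjustment, which runs over the
$k \ge 2$ genes.

**A calibration caveat that is a property of the estimator, not a defect:**
under a true global null with $\tau^2 = 0$, $\hat\tau^2 > 0$ on roughly
half of all draws, which inflates the random-effects SE and shrinks $|z|$.
At the study's scale (4–7 contributing datasets per covariate) the
empirical two-sided type-I error at $\alpha = 0.05$ sits near 0.034–0.037
rather than 0.05 — conservative, never anti-conservative. The test suite
asserts calibration-or-conservatism for this reason; FDR control under the
null is unaffected.

## 2. The pooled risk z-score

The four covariate z-vectors combine as

$$z_{pooled} = \frac{(z_{male} + z_{ppbmi}) - (z_{ga} + z_{bw})}{4},$$

so that positive scores always mean a higher-risk expression pattern
(male sex and maternal obesity are risk-increasing; longer gestation and
higher birthweight are protective). A gene missing from an analysis
contributes a z of zero, and the denominator stays 4 regardless — this
deliberately shrinks pooled scores for sparsely measured genes rather than
inflating their variance, at the cost of attenuating true signals that were
only measurable in a few datasets. Representativeness diagnostics report
the Spearman correlation (average ranks on ties) of each risk-oriented
component with the pooled score and with the mean of the other components.

## 3. Pre-ranked set enrichment

Genes are ranked by $z_{pooled}$ (stable tie-break: metric descending,
then gene id ascending, so runs are reproducible). For a set of size $m$
in a list of length $N$, the running sum rises by
$|r_i|^q / \sum_{hits} |r|^q$ at hits and falls by $1/(N-m)$ at misses;
the enrichment score is the signed extremum. The weight exponent $q$
defaults to 1; at $q = 0$ the statistic is the classic KS form, invariant
to monotone transforms of the metric. If every hit has metric exactly 0
(possible at $q > 0$ on degenerate input), hits fall back to equal
increments rather than dividing by zero.

Because the input is a pre-ranked statistic with no sample-level data,
significance uses **gene-label permutation**: membership is redrawn
uniformly ($m$ of $N$ positions) `nperm` times with the metric fixed. The
normalized score divides the observed ES by the mean |null ES| of matching
sign, and the one-sided p-value is computed within the matching-sign null
with +1 smoothing, bounding p below by $1/(nperm+1)$. The set-size filter
defaults to [10, 500] after intersection with the list; neither the
permutation scheme nor the filter is dictated by the emulated analysis, so
both are documented defaults, not fixed constants.

## 4. RNA-seq replication

Subjects accrue one risk factor per satisfied predicate — gestational age
< 37 weeks, birthweight < 3000 g, maternal pre-pregnancy BMI > 30, male —
with **strict inequalities**: boundary subjects (exactly 37.0 weeks,
3000 g, BMI 30.0) contribute 0. An alternative preset swaps maternal
obesity for cesarean delivery.

Genes with median count below 10 are removed. "Median sum scaling" is
interpreted as rescaling every sample to the median library size: sample
$s$'s size factor is $T_s / \mathrm{median}_s(T_s)$ with $T_s$ the
post-filter total. Each retained gene is then modeled on the raw counts as
negative binomial with $\mu_{gs} = sf_s \exp(\beta_0 + \beta_1\,risk_s)$;
$z_{rnaseq} = \hat\beta_1 / SE$. Dispersion is estimated per gene by
maximum likelihood, falling back to a method-of-moments estimate from a
Poisson fit when the MLE diverges (near-Poisson genes); genes that still
fail are flagged with missing z. No empirical-Bayes dispersion shrinkage or
independent filtering is applied — with ~30 subjects and a single
continuous predictor the per-gene fits are stable, and replicating a
moderation pipeline is out of scope.

The replication score is the plain product $RS = z_{pooled} \times
z_{rnaseq}$ on the gene intersection, passing at $RS > 3$. A rank-based
variant (signed midranks of |z| substituted for the z's) is exposed behind
`use_ranks = TRUE` because the product-of-ranks reading of the score is
also defensible; the product of z's is the default. The cutoff sweep
reports, per cutoff, the passing-gene count (non-increasing by
construction) and the median source-analysis p-values among passers.

Replicating genes are standardized across subjects and summarised by the
first principal component. The sign of a principal component is arbitrary,
so it is fixed by the interpretation that positive subject scores represent
increased expression of low-risk genes: the mean loading of genes with
$z_{pooled} < 0$ is made positive. Constant gene rows are dropped with a
warning. Compositional cell-abundance inputs go through the centered
log-ratio transform; zero parts receive an additive pseudo-count of half
the smallest non-zero part by default (configurable, or an error when
disabled), a choice the emulated analysis leaves open.

## 5. Outcome models

Serum proteins are log10-transformed and standardized to an internal
z-score (sample SD, non-missing values). Binary outcomes (current asthma
from questionnaire conjunctions: diagnosis AND medication-or-wheeze; the
comparison group is no-diagnosis/no-medication/no-wheeze; everyone else
missing) use logistic regression reported as OR per 1 SD with Wald 95%
CIs; continuous outcomes (FEV1/FVC×100, BDR, percentage points) use linear
regression with t-based CIs. Adjustment sets: model 1 = child's birth
characteristics and demographics (gestational age, birthweight-for-GA-and-
sex z, delivery mode, sex, child's race/ethnicity); model 2 = maternal
demographics (PP BMI, race/ethnicity, education, atopy, pregnancy
antibiotics, smoking); model 3 = both, excluding maternal race/ethnicity.
Reference levels: White, never-smoker, vaginal delivery. Analysis is
complete-case per model — outcome-missing subjects are always excluded,
and covariate missingness is handled the same way since nothing in the
emulated analysis specifies imputation.

Relative importance for linear models uses the LMG decomposition computed
by exact subset enumeration (each predictor's average R² increment over
all orderings of entry; a factor's dummies enter as one block, a grouping
choice left open by the source analysis); shares are non-negative and sum
to the full-model R² to numerical precision. Logistic models use McFadden
pseudo-R² drop-one: full-model $1 - \ell/\ell_0$ minus the same quantity
without the predictor. Subset analyses refit the univariate model per
stratum (strata under 10 outcome-complete subjects are skipped with a
warning) and flag heterogeneity when any two strata have disjoint 95% CIs —
a deliberately coarse screen, not a formal interaction test.

## 6. What the simulators emulate — and what they do not

`sim_config()` defaults encode the emulated study design: 11 microarray
datasets of sizes 37, 20, 64, 47, 48, 38, 38, 128, 16, 23, 146 (605
samples) with the published covariate-availability pattern (sex observed
in 6 datasets / 386 samples, gestational age 7/386, birthweight 5/235,
PP BMI 4/164); an RNA-seq cohort of 30 newborns; an outcome cohort of 358
children with true protective log-OR $\log(0.5)$ per SD of the linked
protein and a FEV1/FVC shift of 1.15 points per SD. Covariate marginals
are not published for the source cohorts, so the generators use typical
obstetric ranges, chosen once: gestational age N(39.2, 1.8) weeks
truncated to [24, 42]; birthweight N(3400, 500) g with correlation 0.5 to
gestational age (to exercise correlated-risk-factor behaviour; both
configurable); ordinal PP BMI with probabilities (0.05, 0.50, 0.25, 0.20);
continuous BMI N(25.5, 5.2) truncated [16, 55] where the >30 rule applies.
Signal genes carry a ±1 orientation; a +1 (high-risk) gene shifts by
`signal_effect` residual-SD units per SD of each risk-oriented covariate
and rises with the risk-factor count at log-slope `signal_effect` in the
RNA-seq cohort (default 0.6, a strong but realistic planted effect).
Covariates withheld by a dataset's availability mask still drive
expression — availability is metadata, not biology. RNA-seq baselines are
log-normal (median ≈ 150 counts) so a small fraction of genes genuinely
falls below the median-count filter, library sizes vary 2-fold, and
dispersion defaults to 0.2.

What the simulators deliberately do **not** model: platform-specific probe
intensity distributions, probe→gene many-to-one structure (expression is
simulated at gene level; the max-mean probe collapse in
`preprocess_dataset()` is exercised on constructed fixtures instead),
batch effects beyond a per-dataset baseline shift, cell-composition
confounding, and covariate measurement error. Passing recovery tests
therefore demonstrates that the estimators and plumbing are correct under
the declared generative model — not that real cord-blood cohorts would
yield these effect sizes.

## 7. Numerical conventions and test scale

Quantile normalization is delegated to `limma::normalizeQuantiles` (ties
receive mean reference quantiles), followed by $\log_2(x+1)$; an
all-constant matrix is rejected ("degenerate expression"). Correlations
are clamped to $|r| \le 1 - 10^{-12}$ before `atanh`. Probe collapse keeps
the max-mean row. The streaming enrichment score evaluates the running sum
only at hit boundaries and agrees with exhaustive evaluation to 1e-12;
exact magnitude ties between the positive and negative extremum resolve to
the positive side. DL combination matches a brute-force oracle to 1e-12
and `metafor::rma(method = "DL")` to 1e-10. LMG matches all-orderings
enumeration to 1e-10. Logistic separation is reported as an error when the
predictor's SE exceeds 10 on the link scale.

Test and acceptance runs use the full emulated scale where it matters —
2000 genes × 11 datasets for recovery and null calibration, 100–400
outcome cohorts of n = 358 for Monte-Carlo recovery and coverage — and
smaller grids (hundreds of genes, 4–6 datasets) for property checks, sizes
chosen as the package's own balance of statistical resolution against a
short default test run. All randomness flows from explicit seeds;
identical seeds give byte-identical TSV output.

## 8. Known limitations

* The DL null is conservative at small k (see §1); between-study variance
  is a moment estimate with no Hartung–Knapp adjustment.
* No meta-regression, funnel-plot diagnostics, or publication-bias
  statistics.
* NB dispersion is per-gene with no information sharing; very low counts
  at n ≈ 30 can leave genes flagged as non-converged.
* The outcome models assume the printed covariate codings; with real
  questionnaire data the dummy coding and any transformations would need
  auditing against the source tables.
* Multiple imputation is out of scope; complete-case estimates are biased
  when missingness is informative.
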