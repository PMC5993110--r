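---
title: "Modelling obesity risk from optimized genetic risk scores and expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling obesity risk from optimized genetic risk scores and expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obrisk)
```

## The modelling problem

A cohort carries three layers per sample: effect-allele dosages over a
small panel of BMI-associated SNPs, normalized log-scale expression
profiles, and BMI (kg/m²). The goal is a predictive model of BMI — and
of binary weight status, overweight being BMI ≥ 25 (the WHO convention;
the cutoff is a parameter) — that uses both genetic layers, with every
selection step explicit and reproducible.

The framework assumes SNP effects are additive (the unweighted risk
score is a mean dosage, so every retained SNP contributes equally with
its effect allele oriented toward higher BMI), that expression-BMI
association is adequately captured by a marginal correlation, and that
residual BMI variation is approximately Gaussian for the t-based
inference used throughout.

## The genetic risk score and its optimization

The score of a sample over an included SNP set is the mean effect-allele
dosage, on [0, 2]. Two deliberate choices:

* **Missing calls** use an observed-SNP denominator: a missing call
  leaves both numerator and that sample's denominator. This keeps
  scores on [0, 2] without imputation; a mean-dosage imputation variant
  is available (`missing = "impute"`) for sensitivity checks. A sample
  with no usable call gets `NA` and is flagged rather than silently
  scored.
* **Mean, not sum.** Dividing by the number of included SNPs makes
  scores comparable across iterations of the optimizer, where the
  included count changes; the raw allele count is available as
  `convention = "sum"`.

The optimizer (`greedy_exclude()`) is backward elimination on the
*score*, not on a regression: at each iteration every included SNP is
tentatively removed, the score recomputed, and its correlation with BMI
evaluated; the SNP whose removal gives the largest strictly positive
gain is excluded. Numerical conventions:

* the objective is the **signed** correlation coefficient, because
  effect alleles are BMI-increasing by construction, so the intended
  optimum is positive; `objective = "absolute"` maximizes |r| instead;
* ties between candidate exclusions break to the SNP earlier in panel
  order — any rule works, this one is deterministic and documented;
* `tol = 0` means strictly-greater in exact float comparison; a small
  positive `tol` is available to absorb float noise on near-flat
  objectives;
* a candidate whose score is degenerate (zero variance, or some sample
  would lose its last observed SNP) is treated as non-improving;
* `min_included = 1` stops the walk before the score could become
  empty; in practice convergence occurs much earlier;
* iteration 0 (all SNPs, nothing excluded) is recorded so the trace
  aligns with "number of excluded SNPs" counting.

Greedy elimination optimizes each step, not the subset: it is a lower
bound on the best achievable correlation. `exhaustive_best_subset()`
enumerates all subsets for panels up to 15 SNPs and is used in the test
suite as the oracle bounding the greedy result.

Because the stopping rule accepts *any* in-sample improvement, the
optimizer tends to shed a few genuinely weak signal SNPs once the null
SNPs are gone — the final correlation is an in-sample optimum and is
optimistically biased. Interpreting it as a population quantity
requires external validation; the package deliberately reports the full
trace so this is visible.

## Expression feature selection

Stage one (`scan_genes()`) computes, per gene, the correlation with BMI
and a two-sided p-value via the t transform
`t = r sqrt((n-2)/(1-r²))` on n−2 degrees of freedom, then applies
Benjamini–Hochberg adjustment over all testable genes. Genes with zero
variance are reported untestable and kept out of the BH family so they
cannot dilute it. The significance cutoff is **adjusted p < 0.05**; the
threshold is a parameter.

Stage two (`select_independent()`) orders significant genes by raw
p-value (ties broken by gene ID), seeds the feature set with the best
one, and admits each subsequent gene only if its correlation with every
already-admitted gene is non-significant. The pairwise criterion is a
**raw** p < 0.05 with the same correlation method as the scan: inside a
greedy walk the pair family has no natural BH structure (it depends on
the admission path), so a per-pair test is the defensible choice; the
threshold is exposed. Every decision is logged with the blocking gene,
making the filter auditable: the admitted set is maximal along the walk
order, and each rejected gene names an admitted blocker.

The Spearman variant of both stages uses average ranks for ties and the
same t approximation for p-values — standard at the cohort sizes this
package targets, and swappable in one place (`correlate()`) if an exact
method is ever preferred.

## Integrated models

`fit_bmi_model()` is ordinary least squares of BMI on the admitted
genes plus (optionally) the risk score, with per-term t tests, the
overall F test, and adjusted R² = 1 − (1 − R²)(n−1)/(n−p−1).
Rank-deficient designs error naming the collinear terms rather than
silently dropping them. Backward pruning of predictors at p ≥ 0.05 is
available behind `prune_insignificant` and is **off** by default: a
selected feature set is reported in full unless the analyst explicitly
asks for pruning, since significance-based pruning after selection
compounds selection effects.

`interaction_scan()` refits the main-effects model once per predictor
pair with that single product term added, collects the product-term
p-values and BH-adjusts them across the testable pairs; products
collinear with the main effects are reported untestable.

`cv_classify_weight_status()` classifies the dichotomized phenotype
with a soft-margin SVM (cost C = 1, linear kernel by default; RBF and
polynomial available). Protocol choices that matter for honesty and
reproducibility:

* folds are **stratified by class** and derived deterministically from
  an explicit seed;
* features are standardized with **training-fold statistics only**,
  then the same transform is applied to the held-out fold — margin
  methods need scaling, and doing it globally would leak;
* both the pooled held-out accuracy (correct/total across folds) and
  the per-fold accuracies (with their mean) are reported, since the two
  conventions differ in small cohorts.

## The synthetic cohort generator

`simulate_cohort()` draws the data-generating process the framework
assumes: genotypes from Hardy–Weinberg proportions at per-SNP
effect-allele frequencies; BMI as baseline + additive causal-SNP
effects + planted gene effects + Gaussian noise; planted gene blocks
built from a shared latent factor (`sqrt(rho)·Z + sqrt(1−rho)·noise`),
which hits the target pairwise correlation exactly in expectation;
missingness applied uniformly to genotype calls only (expression
matrices are complete after upstream QC in the kind of study emulated).
All randomness flows from one mandatory seed through per-stage
sub-seeds, so identical configurations reproduce bit-identical cohorts.

Default conditions, chosen once: 500 samples; 27 SNPs of which 10
causal at 0.5 BMI units per allele; allele frequencies cycling through
{0.2, 0.35, 0.5, 0.65, 0.8} (a realistic spread for tag SNPs); 1000
expression profiles — large enough for multiple-testing behaviour to be
real, small enough for hundred-replicate properties — with 5 planted
blocks of 4 genes at within-block correlation 0.8 and 1 BMI unit per
expression unit on each block representative; baseline BMI 26 with
residual SD 3 (an overweight-centred cohort); 2% missing genotype
calls.

What the generator does **not** emulate: linkage disequilibrium between
panel SNPs, population stratification, batch effects, non-Gaussian BMI
(real BMI is right-skewed), and any mechanistic genotype→expression
coupling (so allele-specific-expression scans on simulated cohorts are
null by construction). Passing tests on synthetic cohorts therefore
demonstrate algorithmic correctness and calibration under the assumed
model, not performance on real data.

```{r example}
sim <- simulate_cohort(sim_config(n_samples = 150, n_genes = 100,
                                  seed = 11))
fit <- obrisk_fit(sim$cohort, seed = 11)
fit
```

## Design choices in ambiguous corners

* **Inclusive thresholds.** A sample is removed at ≥ 20% missing
  genotypes ("20% or more"); overweight is BMI ≥ 25.
* **Canonical sample order** after alignment is the phenotype-file
  order; any deterministic order works, this one is documented.
* **Probe-set collapse** keeps the probe with the highest mean
  expression per gene, ties to the lexicographically smaller probe ID.
* **Genotype input** accepts allele-pair strings ("AG", "A/G"; order
  irrelevant) or pre-coded dosages; missing tokens are "", "NA", "./.",
  ".".
* **ANOVA eligibility**: genotype groups with fewer than 2 samples are
  dropped; a test needs ≥ 2 surviving groups, otherwise the pair is
  flagged untestable and excluded from its BH family — untestable and
  testable entries never share a family.
* **Exhaustive subset ties** resolve to the smaller subset, then
  lexicographically — determinism over arbitrariness throughout.

## Problem sizes in the test suite

Unit and property tests run on cohorts of 15–200 samples with panels of
2–12 SNPs and up to 1000 genes; the calibration properties use 100–1000
seeded replicates (greedy parameter recovery at n = 500 × 100 seeds,
BH false-discovery calibration at 1000 replicates of 100 p-values,
permutation-null classification at 100 seeds). These sizes give the
Monte Carlo assertions standard errors well inside their tolerances
while keeping the default suite fast.

## Known limitations

* The optimized correlation and the downstream model R² are in-sample
  quantities after data-driven selection; they are not out-of-sample
  estimates, and no nested cross-validation of the *selection* steps is
  provided.
* The t approximation for Spearman p-values is inaccurate below ~10
  samples; the package refuses correlations below n = 3 but does not
  switch to exact methods.
* The independence filter's per-pair raw-p criterion admits a ~5%
  chance of wrongly blocking an independent gene per comparison; with
  several admitted genes this occasionally blocks an entire correlated
  block's membership.
* No LD-aware SNP handling: panel SNPs are treated as independent
  features.
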