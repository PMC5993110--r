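# obrisk

Predictive modelling of obesity risk from a small SNP panel and blood
gene-expression profiles.

## The problem

Genome-wide association studies have produced reproducible panels of
BMI-associated SNPs, but an unweighted genetic risk score (GRS) over the
full panel often fails to correlate with BMI in a small cohort: effect
sizes differ between populations, and SNPs with no effect in the cohort
at hand only dilute the score. `obrisk` implements a framework for such
cohorts that

1. **optimizes the SNP set** behind the risk score by greedy backward
   exclusion,
2. **selects a small set of mutually independent BMI-associated gene
   expression profiles**, and
3. **integrates both** into a linear model of BMI and a cross-validated
   SVM classifier of binary weight status (overweight: BMI ≥ 25 kg/m²).

It is aimed at biostatisticians working with modest integrated cohorts
(tens to a few hundred samples with genotype, expression and phenotype
layers).

## The methods

**Genetic risk score.** For sample *i* over an included SNP subset *S*,
each SNP contributes its effect-allele dosage (homozygous effect allele
= 2, heterozygous = 1, homozygous other allele = 0) and

&nbsp;&nbsp;&nbsp;&nbsp;G<sub>i</sub> = (Σ<sub>j∈S</sub> d<sub>ij</sub>) / |S|,

a mean dosage on [0, 2]. Missing calls drop out of both numerator and
that sample's denominator.

**Greedy SNP exclusion.** Starting from the full panel, each iteration
evaluates every included SNP and excludes the one whose removal most
increases the correlation (Pearson or Spearman) between the GRS and
BMI; it stops when no removal improves the correlation. The full trace
(iteration, excluded rsID, r, p) is returned, and an exhaustive
best-subset oracle is available for panels of ≤ 15 SNPs.

**Expression feature selection.** Every gene is correlated with BMI;
p-values are Benjamini–Hochberg adjusted over the scanned family. The
significant genes are walked in order of increasing p-value, and a gene
is admitted to the feature set only if it is not significantly
correlated with any already-admitted gene — yielding a small, mutually
independent feature set.

**Integrated models.** BMI is modelled by ordinary least squares,

&nbsp;&nbsp;&nbsp;&nbsp;BMI<sub>i</sub> = α₀ + Σ<sub>k</sub> α<sub>k</sub> E<sub>ik</sub> + β G<sub>i</sub> + ε<sub>i</sub>,

with per-term t tests, adjusted R², and a BH-corrected scan of all
pairwise product interactions. Binary weight status is classified by a
soft-margin SVM (LibSVM via `e1071`) under stratified, seeded k-fold
cross-validation. Validation utilities test allele-specific expression
(one-way ANOVA of a gene's expression across its SNP's genotype groups)
and per-SNP BMI association by correlation, regression and ANOVA.

A seeded synthetic-cohort generator (`sim_config()`,
`simulate_cohort()`) draws Hardy–Weinberg genotypes with a causal
subset, expression with planted correlated gene blocks, and Gaussian
BMI noise, with the ground truth returned alongside — every stage of
the framework is testable end to end without access to any study data.

## Worked example

```r
library(obrisk)

sim <- simulate_cohort(sim_config(n_samples = 200, n_genes = 200,
                                  seed = 1))
fit <- obrisk_fit(sim$cohort, seed = 1)
print(fit)
#> integrated obesity-risk fit (pearson, n = 200)
#>   SNP selection : 15 excluded, 12 retained; GRS-BMI r 0.142 -> 0.399
#>   genes admitted: 4 (G0001, G0007, G0012, G0016)
#>   BMI model     : adj R2 = 0.379 (without GRS: 0.268)
#>   weight status : 5-fold CV accuracy 96.0%

summary(fit$model)
#>          term estimate std_error      t         p
#> 1 (Intercept)  24.1806    1.1603 20.840 2.145e-51
#> 2       G0001   0.9497    0.2222  4.274 3.013e-05
#> 3       G0007   1.1253    0.2337  4.815 2.963e-06
#> 4       G0012   0.9082    0.2446  3.713 2.673e-04
#> 5       G0016   0.8928    0.2298  3.884 1.407e-04
#> 6         grs   7.9214    1.3213  5.995 9.748e-09
#> R2 0.3949 | adjusted R2 0.3793 | model p 1.28e-19 | n 200
```

Reading the output: the all-SNP risk score correlates with BMI at only
r = 0.142; after 15 exclusions the retained 12-SNP score reaches
r = 0.399. Four mutually independent BMI-associated genes are admitted;
adding the optimized risk score to the gene-only regression raises the
adjusted R² from 0.268 to 0.379 (the GRS slope is strongly significant),
and the 5-fold cross-validated linear SVM classifies overweight status
at 96% pooled accuracy on this synthetic cohort. `plot(fit)` draws the
exclusion trace and observed-vs-fitted BMI; `coef()`, `predict()` and
`residuals()` behave as for any fitted model.

File-level use: `run_pipeline()` reads panel/genotype/phenotype (and
optionally expression) tables, applies the ≥20% genotype-missingness
sample filter and sample alignment, fits everything, and writes every
stage artifact plus a JSON report. A thin command-line wrapper lives at
`inst/scripts/obrisk.R` (`simulate` and `run` subcommands).

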