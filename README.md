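# phenoproteo

Molecular phenomapping of high-dimensional plasma proteomics cohorts.

Heart failure (and cardiometabolic disease generally) is clinically
heterogeneous; subgrouping patients by ejection fraction or charted
variables misses mechanistic structure. `phenoproteo` derives **phenogroups**
— patient subgroups defined by unsupervised clustering of plasma proteomics
(aptamer-based, thousands of protein reagents measured in relative
fluorescence units) — and quantifies how stable those groups are and how
strongly they stratify survival. It is written for epidemiologists and
biostatisticians running phenomapping analyses on samples × features
abundance matrices with clinical covariates and time-to-event follow-up.

## The method

Given a strictly positive abundance matrix **X** (n samples × p features):

1. **QC**: drop samples failing explicit lists or per-sample total-signal
   scale-factor bounds; summarise intraassay precision as the per-feature
   CV = 100·SD/mean across replicate measurements (median and IQR).
2. **Transform**: log2, then per-feature z-score (sample SD); the
   per-feature (mean, SD) are frozen for later assignment of new samples.
3. **Reduce**: keep the top 30% of features by median absolute deviation
   MAD(x) = median(|x − median(x)|); form modules as connected components of
   the graph with an edge where |r| ≥ τ (Spearman, τ = 0.7); keep one hub
   per module (largest within-module Σ|r|).
4. **Cluster**: consensus k-means over 80% subsamples; stability scored by
   the proportion of ambiguous clustering
   PAC(k) = F(0.9) − F(0.1) of the consensus-index CDF; k chosen as the
   largest value whose PAC is within 0.05 of the minimum (merging separated
   clusters is itself stable, so the raw argmin underestimates k). Final
   groups from k-means++ with 50 restarts, renumbered by descending size.
5. **Validate & interpret**: in-group proportion (nearest-neighbour
   reproducibility), Rand/adjusted-Rand and optimal-matching concordance,
   hub-randomization / threshold-grid / feature-exclusion sensitivity
   analyses, permutation variable importance against nearest-centroid
   re-assignment, Kaplan–Meier curves (Greenwood log(−log) CIs), reverse-KM
   follow-up, and Cox models with staged adjustment
   (age/sex/eGFR → +log NT-proBNP + MAGGIC → +EF category) and
   likelihood-ratio interaction tests.

A seeded synthetic-cohort generator (`generate_cohort()`) reproduces the
statistical structure this analysis assumes — module-correlated lognormal
abundances, group-graded hazards, coupled clinical covariates — so the whole
pipeline is testable without patient-level data. See the methods vignette
(`vignettes/phenomapping-methods.Rmd`) for models, conventions and
limitations.

## Worked example

```r
library(phenoproteo)

co <- generate_cohort(cohort_config(
  n_samples = 300, n_features = 600, n_modules = 40,
  module_size_range = c(3, 10), n_informative_modules = 10,
  effect_size = 2, seed = 7))

fit <- phenomap(co$matrix, k_range = 2:5, n_resamples = 100, seed = 7)
print(fit)
#> Molecular phenomap
#>   300 samples, 92 selected features (of 92 modules), k = 3
#>   phenogroup sizes: 122 / 101 / 77
#>   k selected by consensus PAC (PAC = 0.0541)

summary(fit)
#> Phenomap summary: k = 3, 92 selected features (92 modules)
#>   sizes: 122 / 101 / 77
#>   PAC by k: 2:0.119  3:0.054  4:0.292  5:0.363
#>   in-group proportion: g1:0.787  g2:0.832  g3:0.584
#>   within-cluster SS: 25952.15

adjusted_rand_index(fit$assignment, co$true_labels)
#> [1] 0.9151356

cox_fit(co$survival, fit$assignment, co$clinical, preset = "M1")
#> <cox_fit> n = 300, events = 223 (Efron ties)
#>         term               hr            p
#>  phenogroup2 2.08 (1.50-2.90) 1.385068e-05
#>  phenogroup3 1.33 (0.94-1.88) 1.101250e-01
#>          age 1.01 (1.00-1.02) 1.891396e-01
#>          sex 0.88 (0.68-1.15) 3.501887e-01
#>         egfr 1.00 (0.99-1.01) 6.354384e-01
```

Reading this: dimension reduction kept 92 hub features; consensus
clustering found three phenogroups (PAC 0.054 at k = 3 vs ≥ 0.119
elsewhere) whose labels agree with the generator's planted groups at
ARI 0.92; the Cox model (adjusted for age, sex, eGFR) shows the planted
hazard gradient across phenogroups. Phenogroups are numbered by size, not
risk, so the highest-hazard group need not be group 3. `predict(fit,
new_matrix)` assigns new samples by training centroids on the frozen
transform scale.

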