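# fibroIndex

Collagen morphometry and a combined fibrosis index for predicting early
recurrence of hepatocellular carcinoma (HCC) after curative-intent
resection.

## The problem

Liver fibrosis raises the risk of intrahepatic HCC recurrence after
hepatectomy, but conventional histological staging (e.g. the Ishak
score) is ordinal, subjective and too coarse to separate patients with
the same stage but different recurrence risk. Second harmonic generation
/ two-photon excitation fluorescence (SHG/TPEF) microscopy images
fibrillar collagen without staining, which makes fully quantitative
fibrosis scoring possible. This package implements that scoring chain
for analysts working with such two-channel images (or with synthetic
imagery standing in for them):

1. **Morphometry** — segment the SHG collagen channel, measure every
   connected collagen "string" (length, width, orientation, area),
   assign it to a region (portal, septal, fibrillar) and pattern
   (aggregated patches vs fine distributed fibers), and emit a canonical
   taxonomy of **100 morphological + 76 relativistic (ratio) features**
   per sample.
2. **Combined index** — min-max normalize features to [0, 1], select a
   subset by **sequential forward selection** under a residual
   sum-of-squares criterion, fit the 0/1 early-recurrence label
   (disease-free interval < 12 months) by **multivariable linear
   regression**, and validate by **leave-one-out cross-validation**
   (LOOCV). For a feature vector `x` the index is

   `index = b0 + sum_j b_j * norm(x_j)`,   high risk iff `index > 0.501`.

   The published 18-feature model (9 morphological, 9 ratio features,
   intercept 3.838) ships as `publishedCombinedModel()` together with
   its 0.501 cutoff.
3. **Outcome statistics** — ROC/AUC with Youden cutoffs, confusion
   metrics, Wilcoxon rank-sum, Kaplan-Meier curves with log-rank tests,
   univariate/multivariate Cox proportional-hazards models (Efron ties,
   Wald CIs), Pearson correlation and per-stratum outcome tables.
4. **Synthetic data** — seeded generators for two-channel images with
   known fiber ground truth, and for 64-patient cohorts whose
   early-recurrence label is driven by a planted linear signal with
   censored survival times — so the entire pipeline is testable without
   any tissue data.

The exact feature enumeration and category cutoffs behind the original
model were never published; the taxonomy here is a documented
reconstruction that totals exactly 100 + 76 features and resolves every
published feature name. Because the original training min/max bounds are
also unpublished, the shipped model reproduces the published linear
arithmetic, not the study's per-patient index values.

## Worked example

Score a patient with the shipped published model:

```r
library(fibroIndex)
m <- publishedCombinedModel()
m
#> LinearIndexModel (combined pool): 18 features, intercept 3.838
#>   risk cutoff: index > 0.501 is high risk
#>   normalization: identity
#>         feature coefficient
#>             SHG       4.300
#>  StrOrientation       1.280
#>       StrAreaPA      -2.413
#>   ...

v <- setNames(rep(0.25, 18), indexFeatures(m))  # normalized features
scoreIndex(v, m)
#> [1] 2.06925
classifyRisk(scoreIndex(v, m))
#> [1] high
```

An index of 2.069 is far above the 0.501 cutoff, so this (artificial)
feature profile is flagged high-risk for recurrence within one year.

Run the full synthetic pipeline (simulate a 64-patient cohort with 22
early recurrences, extract a demonstration image, train an 18-feature
index, cross-validate, evaluate):

```r
res <- runPipeline(pipelineConfig(seed = 1), "run1/")
str(res$report[c("auc_loocv", "sensitivity_pct", "specificity_pct")])
#> $ auc_loocv      : num 0.969
#> $ sensitivity_pct: num 77.3
#> $ specificity_pct: num 100
```

The LOOCV AUC of 0.969 says the retrained index separates the planted
early-recurrence cases from the rest almost perfectly on this synthetic
cohort; `run1/` holds `features.csv`, `model.json`, `scores.csv` (one
LOOCV index and risk call per patient) and a `report/` directory with
ROC and Kaplan-Meier points, confusion metrics, Cox tables and stratum
summaries. Reruns with the same config are bit-identical.

A thin command-line wrapper lives in `inst/scripts/qfibrec.R`
(`run`, `simulate-cohort`, `simulate-image`, `extract-features`,
`score` subcommands).

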