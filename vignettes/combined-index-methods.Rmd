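---
title: "Methods: collagen morphometry and the combined recurrence index"
author: "fibroIndex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collagen morphometry and the combined recurrence index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the feature model, the index construction, the evaluation
statistics, the synthetic-data generators used to validate all of it,
and the numerical and design choices made where the published method
description left the design open.

## 1. The measurement model

### Collagen strings

SHG microscopy images fibrillar collagen directly; the quantification
unit is the *collagen string*, one connected component of the segmented
SHG channel, characterized by

* **length** (µm) — tip-to-tip extent,
* **width** (µm) — mean transverse thickness,
* **orientation** (degrees in [0, 180)) — principal-axis angle,
* **area** (µm²) — pixel count × pixel area.

Strings are cross-classified three ways:

* **region** — portal, septal or fibrillar, by majority vote of the
  component's pixels over user-supplied disjoint region masks. The
  region inference performed on real tissue by the upstream acquisition
  system is proprietary and is *not* reimplemented: masks are an input
  (ground truth for synthetic samples, user-supplied for real images).
  Components outside every mask count only toward whole-image
  ("overlap") features.
* **pattern** — aggregated (component area ≥ 300 µm² by default) vs
  distributed.
* **category** — short vs long (length ≥ 20 µm by default) and thin vs
  thick (width ≥ 3 µm by default). Boundary values always belong to
  the upper class.

The three cutoffs ship in `stringThresholds()` and are configurable
everywhere: the original method states that these categories exist but
never published numeric values, so the defaults are package choices at
plausible tissue scales.

### The 176-feature taxonomy

The published model names its features but never enumerates the full
feature list. `featureTaxonomy()` is a documented reconstruction built
to satisfy every published constraint simultaneously: it totals exactly
100 morphological features, exactly 76 relativistic (ratio) features,
and resolves all 18 feature names printed with the released
coefficients under the naming convention
*measurement + region letter (P/S/F, none = overlap) + pattern letter
(A/D, none = all)*:

* overlap cell: `SHG` (total collagen area %) + 9 string summaries = 10;
* each region: 3 area features (total, `AGG`, `DIS`, as % of imaged
  tissue area) + 9 summaries × 3 pattern cells = 30.

The 9 per-cell summaries are `NoStr`, `NoShortStr`, `NoLongStr`,
`NoThinStr`, `NoThickStr`, `StrArea` (µm²), `StrLength` (mean µm),
`StrWidth` (mean µm) and `StrOrientation`. The orientation summary is
the circular resultant length of doubled angles (1 = perfectly aligned,
0 = isotropic), because a mean angle is undefined for axial data.
Empty cells yield 0 for every summary.

The 76 ratios are the 7 within-cell ratios
(`NoShortStr/NoLongStr`, `NoThinStr/NoThickStr`, `StrLength/StrWidth`,
and the four category fractions over `NoStr`) for each of the 10 cells,
plus the 6 regional area fractions (`AGG`/total and `DIS`/total per
region). A ratio with a zero denominator is reported as 0, which keeps
feature vectors finite on sparse images.

One conflict in the released constants: the ratio
`StrLengthSD/StrWidthSD` is tabulated under the fibrillar region,
contradicting its own S-for-septal naming. The name wins here: the
feature lives in the septal-distributed cell.

### Numerical choices in string measurement

* **Segmentation** (default): global threshold at mean + 2·SD of the
  nonzero SHG intensities, pixels ≥ threshold kept, components < 4 px
  removed. The `>=` makes a binary image map to itself. Otsu
  thresholding is available as an alternative; the method slot is
  pluggable because real-tissue segmentation was not specified by the
  source method.
* **Skeleton**: Zhang–Suen parallel thinning. Parallel thinning erodes
  isotropically (sequential variants shorten oblique fibers), at the
  cost of occasionally fragmenting 2-px diagonal ribbons; the longest
  path search repairs fragmentation by bridging skeleton pieces through
  their closest pixel pairs at Euclidean cost.
* **Length**: the larger of (a) the skeleton longest-path arc length
  under Kulpa step weights (0.9481 straight / 1.3408 diagonal — raw
  1/√2 chain lengths overshoot by up to ~8 % near 22.5°) plus the
  boundary distance at the two path endpoints (thinning stops one
  maximal-disk radius short of each tip), and (b) the pixel extent
  along the principal axis, which is exact for straight structures.
  On randomly oriented synthetic fibers 18–95 µm long and 2–12 px wide
  this estimator stays within ±5 % (±10 % through the full generator
  at 1 µm/px, the tolerance asserted in the tests).
* **Width**: component area divided by the measured length, floored at
  one pixel. A distance-transform estimate cannot distinguish 1-px from
  2-px ribbons and carries a ±1 px odd/even bias; the area budget is
  exact for pixel ribbons of any width.
* **Orientation**: principal-axis angle of the component's pixel
  coordinates via second central moments, folded into [0, 180).
  Angles are measured from the +x (column) axis in image coordinates.

## 2. The combined index

The pipeline mirrors the published construction:

1. **Normalization**: per-feature min–max to [0, 1] learned on the
   training table. Constant features map to 0; unseen values outside
   the learned range are clipped. The shipped published model carries
   *identity* normalization because the original training bounds were
   never released — it therefore reproduces the published linear
   arithmetic (intercept 3.838; all-ones score −3.237), not the
   original per-patient indices.
2. **Sequential forward selection**: greedy, adding at each step the
   candidate minimizing the RSS of the intercepted OLS fit of the 0/1
   early-recurrence label. Ties break toward the earlier feature in
   taxonomy order; candidates that make the design singular are skipped
   with a warning. The source describes no stopping rule, only the
   selected counts, so `kMax` defaults per candidate pool to those
   counts: 18 (combined), 8 (overlap), 11 (portal), 11 (septal),
   13 (fibrillar).
3. **Fit**: ordinary least squares of the 0/1 label on the selected
   normalized features. The regression target is deliberately the
   linear-probability form — no logistic variant is described by the
   source method.
4. **LOOCV**: exactly n fold models, each predicting its held-out case;
   normalization is re-learned inside every fold. Because the source is
   ambiguous about whether feature selection was repeated per fold, two
   modes ship: `"fixed"` (selection once on the full table, coefficients
   refit per fold — the default, matching the apparent published
   procedure, with the caveat that it leaks selection information) and
   `"nested"` (selection redone per fold, leakage-free).
5. **Cutoff**: the published 0.501 applies to the shipped model (strict
   inequality: an index exactly at 0.501 is low risk). How 0.501 was
   derived is unstated, so retrained models instead record the cutoff
   maximizing Youden's J on their training ROC.

## 3. Evaluation statistics

Group comparison of indices uses the two-sided Wilcoxon rank-sum test
(exact enumeration when the smaller group has ≤ 8 values and no ties;
otherwise normal approximation with tie and continuity corrections).
Discrimination uses the empirical ROC with tie-grouped points, whose
trapezoidal area equals the tie-corrected Mann–Whitney statistic — a
property the tests assert against an independent pair-counting oracle.
Survival uses Kaplan–Meier product-limit curves with the log-rank test,
and Cox proportional-hazards models (Efron tie handling, Wald 95 % CIs;
univariate and joint multivariate modes). Monotone likelihoods
(perfect separation) are flagged and their estimates withheld. Stratum
tables report patients, events and percentages to one decimal. These are
standard procedures and are delegated to `stats` and `survival`; the
wrappers fix conventions and output shapes.

## 4. What the synthetic generators emulate

### Images (`generateSample`)

Default geometry scales the acquisition scheme to desk size: square
mosaics of 512-px tiles at 2 µm/px (tests use single 256–320 px tiles
at 1–2 µm/px). The tissue is partitioned into three vertical region
bands; fibers are straight stadium-shaped strokes (round caps pulled in
so the rendered tip-to-tip extent equals the stored truth length) and
aggregated collagen is rendered as filled ellipses above the
aggregation threshold. Structures are placed by rejection sampling with
a 2-px exclusion margin, so ground-truth rows map one-to-one onto
connected components. The SHG channel is 1.0 on collagen plus Gaussian
noise (`noiseSd`, default 0.05); TPEF is a smooth sinusoidal texture
dimmed at collagen sites, carried through I/O but unused by
quantification.

Not emulated: optics (PSF, wavelengths), curved or branching fibers,
fiber crossings, intensity heterogeneity within fibers, and real portal
tract anatomy. Passing morphometry tests therefore demonstrate correct
measurement of isolated, straight, well-contrasted structures — the
regime in which ground truth is defined — not robustness to real-tissue
clutter.

### Cohorts (`generateCohort`)

The default cohort reproduces the modelling conditions: n = 64 with
exactly 22 early recurrences (`prevalenceEarly = 22/64`). Feature
tables are drawn self-consistently (counts additive across categories;
ratio columns computed as actual ratios of the morphological draws;
region areas as Dirichlet splits of the total collagen percentage). A
latent index — a linear combination of four planted features
(standardized, weights (0.8, 0.6, −0.7, −0.5)) plus Gaussian noise
(`noiseSd = 0.4`, leaving the planted signal strongly but not
perfectly predictive) — defines the early label by rank: the top
22/64 fraction. Disease-free times place early cases uniformly below
12 months; non-early cases either recur later (exponential tail whose
rate is linear in the latent index on the log scale) or are censored
(`censorRate = 0.45`). Overall survival adds an exponential
post-recurrence time with log-rate linear in the latent index and
independent uniform censoring — the simplest construction satisfying
the proportional-hazards assumptions the evaluation stage tests. AFP
is lognormal with its log correlated with the latent index at
`afpCorr` (default 0.2, matching the reported weak association);
the correlation target is defined on the log scale because raw-scale
Pearson correlations are attenuated under the lognormal transform.
Clinical covariates (MELD, stages, vascular invasion, tumor size,
cirrhosis) are drawn at the marginal frequencies of the published
cohort tables but carry no planted effect.

Inter-patient variability of real fibrotic architecture is unknown;
the planted-signal model is a stand-in that makes recovery testable,
not a claim about tissue biology.

## 5. Problem sizes and determinism

Every stochastic routine takes an explicit seed and touches no global
RNG state (`withr::with_seed`). The test suite runs morphometry on
single-tile 256–320 px images (3 seeds × 3 configurations for the
ground-truth recovery suite), selection oracles on 50 random 64 × 176
tables plus 10 ten-feature toys, the log-rank null calibration on 1000
permutations, Cox CI coverage on 200 replicates of n = 200, and the
end-to-end discrimination property on 50 synthetic cohorts — sizes
chosen so the full suite completes in about a minute on one CPU while
keeping every stochastic bound at negligible false-failure probability.

## 6. Known limitations

* The 100-feature grid is a reconstruction; a different enumeration
  with the same printed names cannot be excluded.
* The shipped published model cannot reproduce original per-patient
  indices (unpublished normalization bounds); only its closed-form
  arithmetic is verifiable.
* String length for aggregated blobs reports the major-axis extent;
  for highly eccentric ellipses the skeleton-based component of the
  estimator is less accurate than for fibers (the tests assert length
  accuracy for distributed fibers).
* Real-image robustness (stitching seams, overlapping fibers, learned
  segmentation) is out of scope; the segmentation method slot is the
  extension point.
* Competing-risk modelling of recurrence vs death is out of scope;
  disease-free and overall survival are analysed as separate endpoints.
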