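---
title: "Network homogeneity mapping: models, parameters and design choices"
author: "NHfmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network homogeneity mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the network-homogeneity (NH) statistic and the inferential machinery around
it, the synthetic cohorts used to validate every stage, and the design
decisions taken where the methodology leaves genuine freedom.

## The NH statistic

Given a network mask of $N$ voxels and a subject's preprocessed time series
$x_1, \dots, x_N$, the NH of voxel $i$ is its mean Pearson correlation with
the other mask voxels,

$$\mathrm{NH}(i) = \frac{1}{N-1} \sum_{j \ne i} r(x_i, x_j), \qquad
  z_i = \operatorname{atanh}\bigl(\mathrm{NH}(i)\bigr),$$

with self-correlation excluded. `computeNHMap()` standardizes each series
once and accumulates the correlation row-sums through a single inner product
with the column sums of the standardized data, so the cost is $O(NT)$
rather than $O(N^2 T)$; the test suite pins this fast path against a
brute-force double-loop oracle to $10^{-10}$.

Two order-of-operations questions arise and both are settled explicitly:

* **Average-then-transform.** The mean correlation is computed first and then
  Fisher-transformed. The alternative (transform every pairwise $r$, then
  average) is available via `transformFirst = TRUE` but costs $O(N^2)$ and
  is off by default.
* **Clamping.** $|r|$ is clamped to $1 - 10^{-7}$ before `atanh` so that
  degenerate perfect correlations stay finite; the clamp exceeds any
  empirically attainable correlation at realistic $T$.

Smoothing (`smoothNHMap()`, default 8 mm FWHM on 3 mm voxels,
$\sigma = \mathrm{FWHM} / 2\sqrt{2\ln 2}$ per axis) is applied to the z-maps
*after* transformation and *before* group statistics. How out-of-mask
neighborhoods are treated during smoothing is not fixed by common usage; we
smooth with mask renormalization — $\mathrm{sm}(z \cdot m)/\mathrm{sm}(m)$
on mask voxels — so out-of-mask voxels contribute neither signal nor
dilution, constants are preserved exactly, and interior impulses conserve
their mass.

## Preprocessing

The temporal pipeline is fixed as detrend → band-pass → nuisance regression:

* **Motion gate** (`screenMotion()`): exclude when any translation exceeds
  3 mm or any rotation exceeds 3° on any axis; the inequality is strict, so
  exactly 3.0 mm is kept. The narrative rule for such gates says "over",
  and the boundary behavior is tested.
* **Band-pass** (`detrendAndFilter()`, 0.01–0.08 Hz): an ideal
  frequency-domain (FFT) filter, the convention of the DPARSF/REST lineage;
  an ideal filter has no order or ripple parameters to invent, and
  linearity holds to $10^{-10}$. The band must sit strictly inside
  $(0, 1/2\mathrm{TR})$.
* **Nuisance regression** (`regressNuisance()`): OLS residuals against an
  intercept plus the confounds — a Friston-24 motion expansion
  ($[p, p^2, p_{t-1}, p_{t-1}^2]$, first lag row zero-padded), ventricle and
  white-matter ROI means. The whole-brain global mean is deliberately *not*
  regressed (global-signal-preserving analysis). Whether band-pass and
  nuisance regression should be sequential or simultaneous is not fixed by
  the method's common descriptions; we adopt the sequential narrative order
  and note that the regression stage is a plain projection either way.

## Network mask by simplified group ICA

`groupICA()` follows the classic three-step temporal-concatenation scheme:
per-subject PCA reduction of the time dimension, concatenation and a second
PCA to the model order, then fixed-point ICA (logcosh contrast, symmetric
decorrelation) on the whitened data; spatial maps are z-scored. The model
order is fixed at 20 components: published applications of this pipeline
state the dimensionality outright rather than the estimator that produced
it, so we treat it as a parameter, not an estimation problem.
`selectNetworkComponent()` matches components to a template by absolute
spatial correlation (ties to the lowest index; an all-TRUE template
degenerates to the map-mean rule, which is documented rather than hidden),
and `componentToMask()` binarizes at a z threshold, default 1.0 — the
threshold used to binarize such network components is rarely reported, so it
is exposed as a parameter. A user-supplied mask bypasses this module
entirely; the NH machinery is mask-agnostic.

Spatial ICA assumes spatially sparse, near-uncorrelated sources; the test
fixtures honor this (sparse positive supports for recovery tests, dense
heavy-tailed sources for noiseless subspace identities), because strongly
anti-correlated indicator layouts are unidentifiable by any
decorrelation-based method.

## Group inference

`fitVoxelwiseGLM()` fits, per mask voxel, OLS on
$[1, \text{group}, \text{age}, \text{sex}, \text{education}]$ and reports
the two-sided group-contrast t (identical to the pooled two-sample t when no
covariates are entered — an algebraic identity the tests verify
numerically). Covariates are entered untransformed, sex coded 0/1.

`estimateSmoothness()` uses the standard random-field residual estimator:
residuals normalized per voxel, spatial first differences per axis,
$\mathrm{FWHM}_i = \sqrt{4 \ln 2 / \lambda_i}$ voxels, and
$\text{resels} = N / \prod_i \mathrm{FWHM}_i$. `grfClusterInference()`
converts t to z-equivalents (standard at moderate degrees of freedom, and
the Gaussian-field formulas are the ones with closed forms), thresholds at
the two-sided voxel quantile $u = \Phi^{-1}(1 - p/2)$, labels positive and
negative clusters separately (signed cluster formation, matching studies
that report mixed-direction group differences), and assigns corrected
p-values from the expected-Euler-characteristic cluster count
$E[m] = R \,(4\ln 2)^{3/2} (2\pi)^{-2} (u^2 - 1) e^{-u^2/2}$ and the
classic extent law $P(n \ge k) = \exp(-\beta k^{2/3})$ with
$\beta = (\Gamma(5/2)\, E[m]/E[N])^{2/3}$; the two-sided search doubles the
expected cluster count. Cluster connectivity defaults to 26 neighbors (the
DPABI/REST convention) and is a parameter.

**Calibration.** The test suite measures the realized family-wise error on
500 null cohorts (15³ grid, 10 + 10 subjects, whole-grid mask, 60
timepoints — under the null the t-field's distribution does not depend on
the series length, so the calibration uses a short series as a problem-size
choice). Users should know that GRF cluster correction at a 0.001 cluster-
defining threshold is conservative at desk-scale search volumes: the
observed rate sits below the nominal 5%, and a diagnostic that feeds ideal
smoothed Gaussian fields (no NH step) through the same chain is more
conservative still. This is a property of the expected-EC/extent
approximations at small resel counts, shared with the standard
implementations of this correction, not a defect of the surrounding
pipeline.

## Clinical associations

`twoSampleT()` computes pooled or Welch statistics from raw samples or from
printed summary statistics (both reduce to the same closed forms — published
cohort tables mix the two variants in a pattern consistent with a
variance-equality gate, so `cohortComparisonTable()` defaults to choosing
Welch when a two-sided variance-ratio F test rejects at 0.05, and logs the
choice per row). `chiSquare2x2()` is the uncorrected Pearson statistic.

`stepwiseRegression()` is the classic SPSS-style procedure: forward entry of
the smallest partial p at or below 0.05, backward removal of the largest at
or above 0.10, iterated to stability with a cycle guard. Standardized
$\beta = b \cdot s_x / s_y$; with thresholds set to 1 it reproduces the full
OLS model, and a single-predictor standardized β equals the sample
correlation (both tested). Each outcome (three PANSS subscales, eight
cognition scores) gets its own run over the same candidate set (regional NH
features + age, education, duration) in the patient group; no cross-outcome
multiplicity correction is applied, since none is standard in the tables
this layout mirrors. Note the procedure's intrinsic false-entry rate: with
$k$ null candidates remaining, the probability that the final model contains
only the true predictor is about $0.95^k$ (≈ 0.81 for $k = 4$) — a property
of p-gated stepwise selection itself, which the null-simulation tests
document.

## Classification

`rocWithYouden()` builds the exact empirical ROC over all distinct
thresholds (rule: score ≥ threshold ⇒ patient), so the trapezoidal AUC
equals the Mann–Whitney concordance probability with ties counted ½ (pinned
against an exhaustive pair-count oracle and against an independent ROC
implementation). Patients are the positive class; scores are auto-negated
when the raw AUC is below 0.5 (regional NH can run in either direction) and
the flip is recorded. The Youden-optimal cut-off breaks numerically tied J
values toward higher sensitivity, and the accuracy reported at that cut-off
is labelled as Youden-point accuracy — "accuracy" has no other standard
definition for a single continuous marker.

`svmLooAccuracy()` is a radial-kernel soft-margin SVM with leave-one-out
evaluation over the canonical libsvm-style grids
($C \in 2^{-5}, 2^{-3}, \dots, 2^{15}$;
$\gamma \in 2^{-15}, 2^{-13}, \dots, 2^{3}$), feature standardization refit
inside every training fold. By default the $(C, \gamma)$ pair is chosen by
the same LOO estimate that is reported — the common practice with this
library family, which carries a selection-optimism bias; `nested = TRUE`
provides the unbiased per-fold selection at much higher cost.
`subsetSearch()` enumerates all $2^k - 1$ feature subsets, keyed by
concatenated indices ("1", "12", "134", …).

## The synthetic cohort generator

`generateCohort()` plants a shared-factor model: inside region $R$ with
group loading $\lambda$, every voxel series is
$\lambda s_R + \sqrt{1-\lambda^2}\,\varepsilon$ with unit-variance white
Gaussian latent and noise, so the expected within-region pairwise
correlation is exactly $\lambda^2$ — an analytic NH target the acceptance
checks exploit (0.36 at $\lambda = 0.6$). Out-of-network voxels are
independent noise. Band-pass structure is *not* baked into the generator;
the preprocessing stage imposes it, keeping the pre-filter analytics exact.

Defaults (the package's study conditions): a $20^3$ grid of 3 mm voxels,
240 timepoints at TR = 2 s, 20 patients + 20 controls, four disjoint
cuboid regions (~300 network voxels) named after default-mode nodes, with
loadings 0.65 vs 0.45 so that two regions couple more strongly in patients
and two in controls. Regions sit more than one smoothing kernel apart so
planted effects stay inside their region. Demographics are drawn to emulate
a first-episode, drug-naive cohort with matched controls (patients ≈ 31.6 ±
11.4 years, 12.9 ± 3.4 years of education, ~35% male; controls ≈ 28.4 ±
6.9 years, 15.6 ± 2.3 years, ~46% male; illness duration ≈ 2.4 ± 2.7
years), so the confounder code paths are exercised on realistic scales.
Clinical scores are affine functions of regional NH (Fisher-z units), age
and education plus Gaussian residual; `defaultCovariateModel()` wires
negative symptom and general-psychopathology severity to frontal/cerebellar
coupling, processing speed and social cognition to temporal/cerebellar
coupling, attention to age and reasoning to education, with intercepts and
residual SDs chosen so score means and spreads resemble published cognitive
battery tables. PANSS scores exist for patients only; the total is the sum
of its subscales.

What the generator deliberately does **not** emulate: hemodynamics,
physiological noise and its spectra, spatial autocorrelation of the raw
noise (smoothing enters only through the NH map smoothing step), motion
artifacts beyond the parameter tables consumed by the screening gate,
scanner drift beyond a removable linear trend, and between-subject
variability in coupling strength (loadings are fixed per group, which makes
planted group effects strong at $T = 240$ — deliberate, so every stage has
a clean recoverable target). Passing tests on these cohorts therefore
demonstrate the correctness of the statistical machinery, not the field
behavior of the pipeline on real scans.

`generateNullCohort()` replaces every patient loading with the control
loading, making the groups exchangeable — the basis of the family-wise
error calibration.

## Problem sizes and runtime choices

Test and acceptance runs use desk-scale sizes chosen once: $8^3$ grids with
minimal cohorts for the analytic shared-factor checks (20 seeds, $T = 240$);
$15^3$ null cohorts at $T = 60$ for the 500-replicate calibration; $14^3$
grids with 20 + 20 subjects at $T = 240$ for planted-effect recovery (a
30-voxel region, loadings 0.7 vs 0.4, ten seeds); $n = 57$ with four decoys
for the stepwise simulations, matching the patient-group size such analyses
typically have; reduced SVM grids where only structural properties (row
counts, invariances) are asserted, full grids where accuracy itself is the
claim.

## Known limitations

* GRF cluster inference is conservative at small search volumes and a
  0.001 cluster-defining threshold (see Calibration above); permutation
  inference would calibrate better but is out of scope.
* The group ICA is the simplified concatenation variant: no ICASSO-style
  stability analysis, no per-subject back-reconstructed map outputs beyond
  the aggregate mixing matrix.
* The default SVM parameter selection reports the grid-maximal LOO accuracy
  (optimistically biased); use `nested = TRUE` for honest generalization
  estimates.
* Stepwise regression with p-value gates inherits the selection
  pathologies of the procedure (false entries at the per-step rate, biased
  $R^2$); it is provided because it is what this literature reports, not as
  a recommendation.
* Volumes are handled with diagonal affines (axis-aligned geometry); full
  rotation matrices in NIfTI headers are out of scope for synthetic work.
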