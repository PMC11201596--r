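---
title: "Connectome-based prediction of drinking severity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based prediction of drinking severity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netfingerprint)
```

netfingerprint implements a task-based functional connectomics analysis
linking whole-brain connectivity to alcohol-use severity, together with a
synthetic-cohort generator that makes the whole chain testable against
known ground truth. This vignette explains the models, the parameters that
matter, and the design choices taken where the methodology was genuinely
open.

## The severity index

Drinking severity is summarized as the first principal component of a
15-measure consumption battery under **correlation-matrix PCA**: each
measure is z-scored, the sample correlation matrix is eigendecomposed, and
subjects are scored by projection onto the leading eigenvector. The
variance explained is `100 * eigenvalue / m` — for an eigenvalue of 7.42
on 15 measures this identity gives 49.47%, which is what identifies the
correlation (rather than covariance) convention. Battery items where
larger raw values mean *lighter* drinking (e.g. age at first drink) are
sign-flipped before standardization; because the flip set of the original
instrument is not fully determined, it is a user argument
(`flip`), defaulting to the three inverted items of the synthetic battery.
The component's sign is arbitrary, so it is anchored: scores are oriented
so their correlation with a named anchor measure (default: weekly total
drinks) is non-negative. Subjects with any missing measure are excluded
with a warning rather than imputed.

Under a one-factor model in which every measure loads on the latent
severity with loading $\lambda$, PC1's expected variance share is
$(1 + (m-1)\lambda^2)/m$. The generator's default $\lambda = 0.677$ puts
the 15-measure battery at ≈ 49.5%, matching the scale of the real
instrument; this is verified against brute-force eigendecomposition in the
test suite.

## Condition-specific connectivity

Node time courses are taken per task condition: the frames of each
condition's blocks are concatenated (optionally shifted by `lag_frames`;
default 0, since raw block time courses are the reference approach) and
node-by-node Pearson correlations form the connectivity matrix. Fixation
baseline frames are never included. Fisher z is available
(`fisher_z = TRUE`) but raw r is the default feature. Blocks are
concatenated *before* correlating (concatenate-then-correlate), the more
stable choice at short block lengths. A loader for labelled 4-D images is
provided (`extract_node_timeseries()`), averaging voxels within each
integer atlas label per frame.

## Connectome-based predictive modelling

For each cross-validation fold:

1. **Selection.** On training subjects only, every edge's partial Pearson
   correlation with behaviour is computed, controlling age and sex.
   Edges with $p <$ `p_threshold` (default 0.01, the conventional CPM
   default) enter the positive or negative network by correlation sign.
   Selection by p-value is applied as the algebraically identical
   $|r| > r_{crit}$ rule with
   $r_{crit} = \sqrt{t^2/(t^2 + df)}$ at $t = t_{1-\alpha/2, df}$,
   $df = n - 2 - q$.
2. **Strengths.** Each subject's positive and negative network strengths
   are the sums of their edge values over the selected sets.
3. **Model.** Ordinary least squares of behaviour on the strength
   predictors (one for a single network, two for `"combined"`), fitted on
   the training fold; covariates enter selection, not the predictive
   model, matching common CPM practice (switchable via
   `method = "residualized"`, which residualizes behaviour instead).
4. **Prediction.** Held-out subjects are predicted; performance is the
   Pearson correlation between predicted and observed behaviour over all
   subjects. For repeated k-fold, r is averaged over repeats (default
   100 repeats with distinct derived fold seeds).

**Permutation inference** re-runs the full cross-validation on shuffled
behaviour (covariates stay bound to their subjects, so the test isolates
the behaviour–connectome association) and reports
$p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})$. The engine carries
all permuted behaviours through each fold simultaneously, so selection,
fitting and prediction are genuinely repeated per permutation at
matrix-algebra cost. Note that the null distribution of cross-validated r
is considerably wider than $1/\sqrt{n}$ — LOOCV folds share almost all
training data, so fold predictions are strongly dependent — which is
precisely why permutation rather than parametric inference is used. The
permutation p is discrete on the grid $(1+c)/(1+n_{perm})$; calibration
tests therefore compare rejection rates against the exact discrete null
probability rather than the nominal $\alpha$.

**Consensus mask.** For reporting, edges selected in at least a fraction
`consensus` of all folds are retained. The default is 0.90 rather than
1.00: with leave-one-out over hundreds of folds, an edge selected with
per-fold power $p$ survives a 100%-rule with probability $p^{n}$, which is
small even at $p = 0.997$, so a strict intersection has near-zero
sensitivity by construction; a 90% rule is stable while still excluding
chance-level selections. A degenerate training fold (constant strengths,
e.g. empty masks) falls back to an intercept-only model and is counted in
`degenerate_folds`.

## Network anatomy

Selected masks are summarized as node degrees (with the complete
highest-degree set reported — no arbitrary tie-break), 10 × 10
within/between canonical-network edge-count matrices, and the edge
fraction `100 * n_edges / (n_nodes (n_nodes - 1)/2)`. On a 268-node atlas
there are 35,778 unordered pairs, so 39 edges occupy 0.109% — consistent
with a "< 0.11%" specificity bound — while 44 edges give 0.123%, slightly
above a "< 0.12%" bound; the unordered-pair denominator is used throughout
and this small discrepancy in the second bound is simply documented. The
shipped 268-node annotation is synthetic (random network assignments under
a fixed seed); loaders accept real annotation tables.

## Molecular profiling

The regional effect map is a **parcel-level GLM**: per region, OLS of the
regional contrast value on severity, age and sex; T is the severity
coefficient over its standard error. This replaces a voxelwise regression
followed by parcel averaging — the downstream spatial correlation consumes
only regional values, so the regression is run directly at parcel level;
maps are left unthresholded. Spatial correlation computes Pearson r
between the T map and each receptor/transporter density map across shared
gray-matter regions (white matter and CSF excluded; matching is by region
label, never row order), with two-tailed parametric p-values and a per-map
$\alpha = 0.05$ flag, the convention of the reference toolchain. No
spatial-autocorrelation (spin) correction is applied; a
multiple-comparison flag (`p_adjust`) is available, and it matters: with
27 maps and 25 true nulls, the per-map rule flags at least one null map in
$1 - 0.95^{25} \approx 72\%$ of datasets, so *exact* identification of a
planted pair of associations is only achievable under familywise control
(Holm), while the per-map rule is what keeps the null calibration at 5%.
Both behaviours are exercised in the tests. Density maps are linearly
rescaled to \[0, 100\]; the rescale is affine, so correlations are
unchanged.

## The synthetic generator

`sim_config()` defaults emulate the study conditions: 981 subjects
(ages 27.9 ± 3.6 for men, 29.6 ± 3.6 for women; 51.8% female), a 268-node
atlas, two runs of a gambling task with two reward and two punishment
blocks each (38 frames per block, i.e. ≈ 28 s at TR 0.72 s, four blocks
per condition in total), a 15-measure battery with factor loading 0.677,
and ten positive plus ten negative planted edges with baseline
connectivity 0.2 and effect size 0.2 per SD of severity.

Planted edges respond to a subject-level factor
$u_i = \rho\, s_i + \sqrt{1-\rho^2}\,\eta_i$, where $s_i$ is the latent
severity and $\eta_i$ independent individual variation shared across a
subject's planted edges. The **coupling** $\rho$ caps the attainable
brain–behaviour correlation. This is essential for realism: with
independent per-edge noise, summing ~20 edges into a network strength
averages the noise away and the population prediction r saturates near 1
whenever individual edges are detectable. Real cohorts show the opposite
pattern — detectable edges but modest prediction — because connectivity
varies between subjects for many reasons besides the behaviour of
interest, and $\eta$ models exactly that. The closed-form oracle
`expected_prediction_r()` decomposes the attainable prediction r as
$\rho \times A \times b$ (coupling × strength reliability × PC1 proxy
factor) and is verified by Monte-Carlo in the tests; the default
$\rho = 0.26$ was chosen from this oracle so the population-level
prediction r is ≈ 0.25 at the default design. Planted edge pairs are
node-disjoint by default, so the target correlation matrix decomposes
into 2 × 2 blocks that are positive definite for any admissible planted
value; arbitrary targets are repaired by eigenvalue clipping at a floor
of $10^{-6}$ followed by diagonal renormalization, iterated to
convergence, and a repair that would move a planted edge by more than
0.05 aborts naming the offending edges.

The generator's noise is Gaussian and i.i.d. across frames: no
hemodynamic autocorrelation, scanner drift, motion, or physiological
artefacts. Severity enters edge correlations linearly, matching CPM's
linear detection model so parameter recovery is interpretable.
Consequently, passing tests demonstrate that the statistical machinery is
correct and calibrated — they do not demonstrate robustness to the
preprocessing realities of real fMRI, which are upstream of this package's
scope.

## Problem sizes and numerical choices

Worked examples and validation runs use desk-scale cohorts chosen to keep
the full chain quick while preserving the statistical regime of interest:
null-calibration suites use 300 subjects on a 60-node atlas with 99
permutations per test (the permutation grid is then 0.01-spaced);
recovery suites use 500 subjects, 60 nodes and 20 replicate seeds; the
demo pipeline uses 200 subjects. Constant edges are excluded from
selection (r set to 0, p to 1); near-zero residual variance in the parcel
GLM is flagged as a perfect fit and capped at the largest finite T of the
map's sign; Pearson r at ±1 propagates to ±Inf under Fisher z, which is
left to the caller. All randomness flows through explicit integer seeds:
stage seeds are derived from a single master seed by hashing, so a
pipeline config reproduces every output bit-identically, as the manifest
records.

## Limitations

- The spatial correlation treats regions as exchangeable; spatially
  autocorrelated maps will inflate parametric significance, and no spin
  test is provided.
- The synthetic atlas annotation is random; anatomy summaries on it are
  structurally correct but anatomically meaningless.
- k-fold prediction r is reported as the mean over repeated splits;
  single-split values can differ noticeably at these sample sizes.
- LOOCV at large n is the slowest configuration; repeated 5-fold gives
  similar answers at a fraction of the cost and is the default for the
  permutation-heavy calibration suites.
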