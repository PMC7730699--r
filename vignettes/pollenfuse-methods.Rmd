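---
title: "Methods: sensometric fusion of colour, NIR, e-nose and e-tongue data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensometric fusion of colour, NIR, e-nose and e-tongue data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenfuse)
```

pollenfuse implements a complete sensometric fusion pipeline for bee
pollen: colour characterization, instrument-block pretreatment,
classification by botanical origin, regression of sensory and colour
attributes from single blocks and from their low-level fusion, and the
panel statistics that validate the sensory reference data. This
vignette explains the models, the tunable parameters, the synthetic
data the tests run on, and the numerical choices made where the design
was genuinely open.

## Colour arithmetic

Instrument readings are taken as given CIELAB coordinates; no
reflectance-to-XYZ conversion or illuminant modelling is attempted.
Chroma and hue angle are the polar form of the chromatic plane,
`C*ab = sqrt(a*² + b*²)` and `h_ab = atan2(b*, a*)` in degrees on
[0, 360). Colour differences between sample means are the Euclidean
ΔE*ab, the absolute chroma difference ΔC*ab, and the absolute hue-angle
difference Δh_ab taken on the circle as `min(d, 360 − d)`. Δh is the
plain angular difference, not the CIE ΔH*ab chord metric: the angular
convention reproduces the published pairwise tables for these samples,
which the chord metric does not.

Two degenerate cases are fixed by convention: the achromatic point
(a* = b* = 0) has hue 0°, and the perceptibility categories
("not perceptible" < 1.5 < "perceptible" < 3.0 < "well perceptible"
< 6.0 < "huge") are closed on the left, so a ΔE of exactly 1.5 is
"perceptible". The source thresholds are stated with strict
inequalities on both sides, which leaves the boundary points
unassigned; closing on the left is an arbitrary but deterministic
completion, and boundary behaviour is pinned by tests.

All derived values are computed from unrounded inputs. When comparing
against published tables (whose entries are rounded to 1–2 decimals),
tolerances of ±0.05 on chroma/hue, ±0.01 on ΔE, ±0.05 on ΔC and ±0.1
on Δh reflect that rounding; exact agreement of ΔC at two decimals
cannot be guaranteed from rounded inputs, only to within ±0.05.

## Block pretreatment

**Savitzky–Golay smoothing** (`savgol_smooth()`, default order 2,
window 21 points, no derivative) replaces each spectral point by the
value of the local least-squares polynomial. At spectrum ends the
polynomial is fitted on the truncated asymmetric window and evaluated
at the point itself, rather than padding or reflecting the signal —
no data are fabricated beyond the measured range, and polynomials up
to the fit order remain exactly invariant across the whole spectrum,
ends included. Interior points equal the classical convolution
stencil, which the test suite cross-checks against an independent
filter implementation.

**Multiplicative scatter correction** (`msc_correct()`) regresses each
spectrum on a reference (default: the block's mean spectrum) and
returns `(x − intercept)/slope`. The reference is returned so held-out
spectra can be corrected with the training reference. The NIR range is
then truncated to the closed interval 950–1650 nm, dropping the noisy
instrument edges.

**E-tongue drift correction** (`drift_correct_etongue()`): the cited
drift-correction procedure ("additive correction relative to all
samples") is not specified by formula in the source literature
available here, so it is implemented literally as per-sensor,
per-session additive re-centering: every session measures the full
sample set, so the session mean over all samples estimates the
sensor's ageing offset, and subtracting (session mean − grand mean)
removes it while preserving all within-session contrasts exactly and
the per-sensor grand mean. This is a declared reading of the method,
not a vendor-verified reimplementation.

**E-nose sensor selection** (`select_sensors_by_discrimination()`):
discrimination power is the Fisher ratio, between-class over
within-class sum of squares per sensor, with ties broken by sensor-id
lexical order. The instrument vendor's exact formula is undocumented;
the Fisher ratio captures the stated definition (minimum variability
within a group, maximum between groups), and the pipeline's guarantees
are about the induced ranking, not about matching vendor numbers.
A constant sensor scores 0; a perfect separator scores infinity.

**Autoscaling** (`autoscale_fit_apply()`) uses the n−1 standard
deviation throughout and refuses constant training columns by name.

## Classification

LDA uses the pooled within-class covariance. Spectral blocks have far
more variables than observations, so when a training set is wider than
it is tall the block is first compressed to PCA scores retaining 99%
of the training variance, capped at `n_train − n_classes` components;
held-out rows are projected with the training loadings, so no
information leaks across folds. Threefold cross-validation is
stratified by class with a fixed default seed (42) that is reported in
the result; stratification and seed are implementation choices, as the
source protocol does not state them. Recognition (resubstitution) and
prediction (cross-validated) abilities are macro-averages of per-class
accuracies, matching the per-class misclassification narration of the
study. If the pooled covariance is singular even after compression,
a ridge of `1e-8 ×` the mean diagonal is added.

## Regression

`fit_plsr_nipals()` implements univariate-response NIPALS: each latent
variable's weight vector maximizes covariance between X scores and the
response, scores are deflated from both X and y, and the weight sign
is fixed so its largest-magnitude element is positive (NIPALS is
sign-indeterminate). With as many latent variables as the rank of X
the model equals ordinary least squares, which the tests assert at
1e-8.

`crossval_plsr()` runs leave-one-sample-out grouped cross-validation:
a group is one preparation unit (all scans/repeats of one sample
replicate, 15 units in the default design), so no unit ever predicts
itself. The latent-variable count is chosen at the minimum of the
RMSECV curve, never exceeding the number of units or the training-fold
rank. R² uses `1 − SSE/SST` with SST about the mean; cross-validated
R² may be negative and is reported unclipped (published tables contain
a −0.25). RPD is `SD(observed)/RMSECV` with the n−1 SD, so internally
`RPD = sqrt(1/(1 − R²CV)) · sqrt(n/(n−1))` holds exactly — the
relation the acceptance checks exploit, allowing for the two-decimal
rounding of published R²CV values.

Centering and scaling inside cross-validation are fitted on training
folds only (the NIPALS fit centers on its training rows; `scale_x`
scales there too). For the NIR block the MSC reference is likewise fit
per training fold through a pretreatment hook
(`pretreat_scope = "training"`, the default); `"full"` reproduces the
single whole-block pretreatment mode. The difference is negligible on
the synthetic study but the leakage-safe default is the defensible
one.

## Fusion and the two-round procedure

`align_blocks()` builds the fused matrix on the NIR row basis: within
a preparation unit, e-tongue rows are paired with NIR scans in
acquisition order and the unit average fills in when the e-tongue has
fewer rows; the unit's single e-nose row (the 5 mL / 60 °C headspace
method, the best-discriminating one) is replicated across the unit's
NIR scans. Columns are concatenated and autoscaled after
concatenation; the scaler and a column→block map are kept so any
block's aligned content can be recovered exactly. The fused row count
is data-dependent — the pipeline makes no attempt to hard-code the
specific observation counts of the original study, which resulted from
outlier removal on data that are not published.

`two_round_plsr()` fits a first grouped-CV model on all rows, screens
its cross-validated predictions with a per-sample boxplot, removes
flagged rows and refits. The whisker rule is median ± 1.5·IQR as the
study words it — note this is anchored on the median, not the classic
Tukey quartile-anchored whiskers; `rule = "tukey"` provides the
classic variant. Values exactly on a whisker are retained. Screening
is per predicted attribute, so different attributes may retain
different observation counts. Because a held-out unit's prediction
never sees its own response, this screening catches observations whose
*signal* is anomalous (a corrupted or swapped scan producing a
prediction outside its sample's cluster); a response-side anomaly with
a clean signal is invisible to it, a property the tests document by
construction.

## Sensory statistics

Per attribute, a fixed-effects two-way ANOVA
`score = sample + assessor + sample:assessor` is fitted on the
balanced 14-panellist × 2-session × 5-sample design, and sample means
are compared with Tukey's HSD computed from the residual mean square.
The compact letter display uses insert-and-absorb on means sorted
descending; with a single common HSD the letter groups are the maximal
runs of consecutive means within one HSD of each other. The residual
root mean square doubles as the panel repeatability index. Mixed
assessor model decompositions (scaling/disagreement F statistics) are
third-party panel-software output and are out of scope; plain two-way
ANOVA plus residual RMSE is the reproducible surface.

`oneway_anova_from_summary()` reconstructs the one-way F test from
published per-sample means and SDs: published SDs are treated as
sample SDs (n−1 denominator) with n = 28 scores per sample-attribute
cell. On balanced data this equals the F computed from raw
observations, which the tests verify. Applied to the packaged
18-attribute summary table, exactly 17 attributes discriminate between
samples at α = 0.05, with aftertaste intensity the sole exception
(F ≈ 2.09 against a critical value of ≈ 2.44).

## The synthetic study generator

No public data accompany the original study, so `generate_study()`
draws a five-class study with the design's dimensions (5 botanical
classes × 3 preparation replicates; 5 consecutive NIR scans per
replicate, n = 75; 4 e-tongue sessions, n = 60; one e-nose row per
unit, n = 15; 10 colour readings per class; 14 panellists × 2
sensory sessions) and the statistical structure the analysis assumes:

- **Colour and sensory class means** come from the packaged published
  summary tables, with Gaussian noise at the published SDs (sensory
  residual noise at 0.6 of the published within-sample SD plus
  additive panellist effects of SD 2 — additive only, since scaling
  heterogeneity is out of scope).
- **NIR** spectra are a water-dominated base with Gaussian bands whose
  class-dependent amplitudes are concentrated at 1364 and 1450 nm
  (free vs hydrogen-bonded water), smaller variation at 1163, 1415 and
  1495 nm, per-scan multiplicative gain U(0.9, 1.1) and additive
  offset (removable by MSC), and white noise of SD 0.002 absorbance.
- **E-tongue** signals place the two Carduus-containing polyfloral
  samples (lakeshore bulrush, spiny plumeless thistle) close together
  (within a few noise SDs) and the unifloral samples far apart, plus
  an additive per-session drift vector of SD 10 shared by all
  observations of a session. Drift draws are standard normals scaled
  by the drift SD, so a zero-drift twin study is exactly the same data
  minus the drift — the property the exact-removal tests use.
- **E-nose** pools 59 sensors of which 20 carry class patterns with
  linearly graded separation (hence graded Fisher ratios); the rest
  are noise.
- **Attributes for regression** are generated per preparation unit as
  the class mean plus `0.25 × S` times each of three unit-level latent
  factors (S the attribute's between-class SD) plus `0.05 × S` noise.
  One latent factor is expressed in each instrument block, which is
  precisely what makes fusion informative: any single block misses two
  of the three factors, the fused block sees all three. The e-tongue
  latent loading is chosen orthogonal to the polyfloral pair's mean
  difference so unit-to-unit variation does not blur the one
  deliberately confusable class pair.

These separations and noise scales were fixed once, as the realistic
regime in which the study's qualitative outcomes emerge (NIR and
e-nose classification at ceiling, e-tongue confusable only within the
polyfloral pair, fused regression dominating single blocks); they are
design constants of the generator, not quantities fitted to any data.
All randomness flows from one master seed through fixed per-block
sub-seeds.

What passing tests on this generator do **not** show: real NIR spectra
have richer band structure and correlated noise; real sensor drift
need not be purely additive; real attribute–instrument relationships
are not exactly linear in three latent factors. The generator
demonstrates that the pipeline recovers structure it is designed to
recover — it cannot certify performance on real instruments.

## Problem sizes and determinism

The test suite and the acceptance script run the full study
orchestration (4 blocks × 23 attributes × two PLSR rounds, plus
per-block PCA/LDA) at the design's native size, about ten seconds per
seed, and repeat it over five seeds for the fusion-dominance property.
Stochastic properties (chance-level classification, noise-floor
recovery, outlier-rule recovery) use 10–50 fixed seeds each. Every
simulation is reproducible from its stated seed; package functions
that accept a seed restore the caller's RNG state.

## Known limitations

- PLS1 only; each attribute is regressed independently (no
  multi-response PLS2, no OPLS/kernel variants).
- Low-level (concatenation) fusion only; no mid- or high-level fusion.
- The drift-correction and sensor-selection procedures are declared
  readings of instrument-vendor methods whose exact formulas are not
  public.
- The compact letter display assumes the single common HSD of a
  balanced design.
- Sensor identifiers are opaque labels: no Kovats-index computation or
  aroma-compound assignment is attempted.
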