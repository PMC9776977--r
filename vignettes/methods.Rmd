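---
title: "Methods: local ADC radiomics and the csPCa signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local ADC radiomics and the csPCa signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(adcradiomics)
```

This vignette documents the modelling choices behind `adcradiomics`: the
pipeline's statistical definitions, the parameters that matter and their
defaults, what the synthetic cohort generator does and does not emulate, and
the numerical conventions a reader needs to reproduce results exactly.

## The pipeline

The package predicts clinically significant prostate cancer
(csPCa, Gleason Grade group ≥ 3) from a single ADC slice per patient plus a
gland mask and lesion ROIs. The stages are: local first-order parametric
maps → 132-feature lesion vectors → min–max normalization → two-stage
selection (weighted LASSO screen, exhaustive 4-feature linear-SVM search) →
feature-space augmentation and a stratified 75/25 split → repeated-CV SVM
training with Bayesian hyperparameter search and logit score calibration →
confusion/ROC reports, plus a Gleason-group similarity analysis of the
scores.

## First-order statistics: exact definitions

All statistics operate on a pixel sample (a window, or a lesion's pixels):

* mean, median (type-7, linear-interpolation percentile);
* population standard deviation σ (denominator *n*; the sample convention is
  a switch, `sample_var`);
* coefficient of variation cv = σ/mean, defined as 0 when the mean is 0;
* moment skewness m₃/m₂^1.5 and Pearson (non-excess) kurtosis m₄/m₂², with
  the constant-sample conventions skewness = 0 and kurtosis = 3 (both
  logged);
* IQR = P75 − P25, type-7 percentiles;
* unscaled MAD = median(|x − median(x)|);
* Shannon entropy −Σ pᵢ log₂ pᵢ (bits) and uniformity (energy) Σ pᵢ² over a
  fixed histogram of 32 equal-width bins.

**Histogram support.** The bin count and support are the one genuinely
underdetermined piece of a first-order pipeline. Local maps share one
support per image: the gland-wide intensity range, so neighbouring windows
are comparable. Global descriptors of a map likewise bin over that map's
gland-wide range of defined values (and raw-ADC descriptors over the gland's
ADC range). The alternative — binning each lesion sample over its own
range — makes uniformity and entropy *shape-only* statistics, blind to how
concentrated a lesion is relative to its gland; with gland-wide support,
`mu-u` (uniformity of the local-mean map) measures exactly the "uniform
local means" property the signature exploits. Bin count (32) is a config
key; results are insensitive to it between 16 and 64 in our tests only in
the sense that the test suite's patterns hold — absolute feature values do
change.

**Window support rule.** A pixel's window (default 9 × 9; odd sizes only) is
intersected with the gland; the pixel is undefined when fewer than 50% of
the window's pixels lie inside the gland (border pixels count as outside).
The 50% threshold (`min_support`) is our convention — the reference method
does not state one — and matters mainly for small or rim-adjacent lesions,
which can lose all defined pixels and are then excluded with a logged
reason (never silently).

**Last decile.** The descriptor pair `d-mean`/`d-median` averages the
subsample at or above the type-7 90th percentile, ties included. For
`1:10` the last decile is `{10}`.

**Lesions spanning several slices** pool their pixel samples (and bin
supports) by `lesion_id` before the descriptors are computed; a per-slice
mode falls out of simply giving slices distinct ids.

## Selection

Normalization is fitted on the full selection cohort (matching the
reference ordering, normalization before selection); a leakage-safe variant
accepts pre-fitted parameters from a training subset. The LASSO screen is a
binomial `glmnet` path (100 λ values, `standardize = FALSE` because inputs
are already min–max scaled) with stratified 10-fold CV at the
minimum-deviance λ. "Weighing each sample by the prior probability of its
membership class" is ambiguous — taken literally it would *down-weight* the
minority class — so the default is inverse-class-frequency (balanced)
weights, with the literal prior weighting available
(`weighting = "prior"`).

The exhaustive stage fits one linear SVM (C = 1, γ = 1) per 4-combination,
tests the decision values between classes with a two-sided Wilcoxon
rank-sum, corrects with Holm–Bonferroni across **all** combinations at
α = 10⁻³ (whether the reference corrected over all or only reported
combinations is unstated; all is the conservative reading), and the winner
maximises informedness at the native zero threshold, with ties broken by
smaller p, then lexicographic feature names.

## The SVM and its search

No SVM implementation ships with this R installation, so the classifier is
the textbook soft-margin SVM solved as the *primal* QP with `quadprog`:
minimise ½‖w‖² + C Σξᵢ subject to yᵢ(w·xᵢ + b) ≥ 1 − ξᵢ, ξᵢ ≥ 0, on inputs
divided by the kernel scale γ (the "linear scale" of the two-parameter
search; for a linear kernel it is redundant with C but is kept explicit to
mirror the reference's search space). The primal is used instead of the
dual because the linear kernel matrix has rank ≤ 5 and the dual then needs
a solution-distorting ridge; the primal only needs a negligible (10⁻⁸)
curvature on b and ξ to satisfy the solver. The test suite cross-checks
weights and intercept against scikit-learn's `SVC`.

Hyperparameters are searched per CV run over log₁₀C, log₁₀γ ∈ [−4, 3] by a
small Gaussian-process expected-improvement optimizer (squared-exponential
kernel, fixed length scale 0.25 on the unit square, 30 iterations by
default — the reference names the algorithm family but no budget). Within a
run, the three fold models at the chosen (C, γ) are filtered by the
overfitting rule (validation AUC must not exceed training AUC), the best
surviving fold model is kept, survivors across runs are re-scored on the
entire training set and ranked by (AUC, informedness), and the top model's
decision values are calibrated with a binomial-logit (Platt-type) fit;
a non-convergent or non-monotone fit falls back to the unscaled logistic
(A = 1, B = 0) and is flagged.

## Augmentation and split

The reference augments via an external procedure it does not describe; we
implement within-class pairwise interpolation (SMOTE-like): a synthetic row
is x_i + λ(x_j − x_i) with x_j one of the 5 nearest same-class neighbours
and λ uniform on [0.05, 0.95], so originals are retained, synthetic rows
stay in the per-class convex hull, and no original is duplicated. Gaussian
jitter is the config alternative. The split is stratified with exact class
balance (200 → 75 + 75 / 25 + 25). The "SVM margin rule" is read through
its worked behaviour — the samples nearest a pilot SVM's boundary all land
in training — so the margin rule fills the training quota in ascending
|decision value|; a plain stratified random split is the default. Whether
the reference augmented before or after splitting is unstated; the pipeline
default splits the original lesions first and augments the pools
independently (no synthetic leakage across the split), and the
reference-faithful augment-then-split mode is a flag. The augmented test
set of the faithful mode shares interpolation parents with training — its
AUC is accordingly optimistic, which is worth remembering when comparing
with the no-augmentation ("preliminary model") pathway, which runs the
identical downstream code on the 117 original lesions.

## Similarity analysis

Scores for the group analysis are the decision values of a linear SVM on
the four selected features over all original lesions. Tests: Kruskal–Wallis
(χ² approximation, tie-corrected) across GG1/GG2/GG3, GG1/GG2/GG≥3 and
within GG≥3 (GG3/GG4/GG5 — the reference does not name the test for its
within-GG≥3 comparison; Kruskal–Wallis is assumed); one-tail Wilcoxon
rank-sum pairwise with the alternative "the higher group scores higher"
(the direction of the monotone group medians); Ansari–Bradley on
median-removed samples for dispersion, α = 0.05 (location tests use
α = 10⁻³). Mid-ranks with tie corrections are used throughout; exact
enumerations back the small-sample tests in the suite.

## The synthetic cohort: what it states, and what it cannot

The generator reproduces the reference cohort's structure exactly: Gleason
counts 25/36/21/23/12 over 102 patients (117 lesions, the largest assigned
one per patient), log-uniform lesion areas on 8–1655 px (median ≈ 104 px,
matching the printed median), 0.78 mm pixels, elliptical glands, and
benign-gland ADC near 1400 (the printed lesion-area/mm² correspondence
fixes the spacing). Lesion texture is a two-level Gaussian tile model —
9 × 9 tiles with per-tile means around a lesion mean, per-pixel noise with
per-tile SDs — which is the literal mechanism of the reference's
within-unit/between-unit narrative: GG ≥ 3 lesions have uniform local means
(small between-tile SD) and high, spatially uniform local variance (high
within-tile SD, small per-tile jitter); GG < 3 lesions are the opposite.
GG1 and GG2 draw from one distribution (the built-in negative control), as
do GG3/4/5.

Three per-lesion random effects were required to express the reference's
*printed* distributional facts and are part of the stated world, fixed
before the acceptance suites were run: (a) each lesion draws its own
between-tile SD and within-tile SD level (lesions of one class differ in
how strongly they express their class), (b) a small blend (≤ 0.08) toward
the opposite class's parameters emulates the biological continuum between
Gleason growth patterns, and (c) a multiplicative noise-scale nuisance
(0.7–1.4), shared by both classes, emulates patient-to-patient variation.
Without these, the GG ≥ 3 lesions collapse onto a near-degenerate point of
feature space — incompatible with the comparable group variances
(σ² ≈ 2.9/2.5/2.6) and the ≈ 0.88 operating AUC the reference prints.

What the generator does **not** emulate: anatomy (no zonal structure, no
lesion-shape irregularity beyond ellipses), MRI physics (Gaussian, not
Rician, noise), scanner/protocol drift, segmentation error, and biopsy
label noise. A green cohort-level test therefore establishes that the
pipeline recovers planted statistical structure of this specific form — not
clinical performance.

**A known structural limitation.** In this world, GG < 3 is *defined* by
heterogeneity, and the expression of heterogeneity grows with lesion size;
along any heterogeneity-reading discriminant the GG < 3 group is therefore
intrinsically more dispersed than GG ≥ 3. The Ansari–Bradley comparisons of
GG1/GG2 against GG3 consequently flag dispersion differences in a
substantial fraction of cohort realisations, although the GG1-vs-GG2
comparison and the full location pattern are stable. The reference's
comparable group variances evidently reflect within-class variance sources
(histologic diversity, acquisition variation) beyond what a two-level tile
texture can carry; the corresponding dispersion check in the test suite is
kept at its stated form rather than weakened, and may fail for this reason.

For the planted-feature recovery check, the "planted families" are assigned
empirically rather than by name: two single-contrast cohorts (one where
only the within-tile variance axis differs between classes, one where only
the between-tile mean-structure axis differs) are generated at double size,
and a feature joins a family when its marginal |AUC − 0.5| ≥ 0.10 there.
Recovery means the chosen quadruple reads both planted axes — under the
heavy collinearity of 132 first-order features, demanding the four named
features would test tie-breaking, not selection.

## Numerical conventions worth knowing

* Percentiles: type 7 (linear interpolation) everywhere.
* Report rounding: percentages round half up to integers; informedness and
  AUC to two decimals. Fractional values are retained alongside.
* AUC: rank-sum (Mann–Whitney) formulation with mid-rank ties — identical
  to the trapezoid on the empirical ROC. The 95% CI is a stratified
  percentile bootstrap (2000 replicates; the reference's CI method is
  unstated, DeLong-free bootstrap is the default).
* Degenerate inputs: constant features are dropped at normalization (with a
  log entry); single-class metric reports carry `NA` for the undefined
  rates; an all-discarded training run relaxes the overfitting filter with
  a warning rather than failing.
* Determinism: every stochastic stage takes a seed; `run_full()` derives
  stage seeds from the master seed, and rerunning a config reproduces the
  feature table and model JSON byte for byte.
* I/O: NIfTI-1, 16-bit single-strip TIFF and single-frame little-endian
  DICOM (read-only, rescale slope/intercept applied) are implemented
  directly against the format specifications — no imaging I/O package
  exists in the dependency environment — and are cross-checked against
  nibabel and tifffile in the test suite. ImageJ `.roi` polygon import is
  not provided; masks are the contract.
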