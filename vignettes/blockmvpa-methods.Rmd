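---
title: "Decoding and individual-difference prediction for block-design fMRI: methods and design choices"
author: "blockmvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{blockmvpa methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`blockmvpa` implements a complete multivariate analysis chain for
block-design fMRI of the why/how social-inference paradigm (and structurally
similar paradigms): a task contrasting mental-state inferences ("why is this
person doing that?") with factual perceptual judgments ("how is this person
doing that?") on identical stimuli, presented in blocks crossed with target
categories (emotional faces, intentional hand actions, optionally nonsocial
scenes).

The chain has three statistical stages.

1. **Block-wise GLM.** Each task block gets its own boxcar regressor
   (spanning the onset of its first target image to the offset of its final
   image), convolved with the canonical double-gamma HRF and sampled at the
   TR. Nuisance terms: a discrete-cosine drift basis implementing a 1/100 Hz
   high-pass cutoff, the six rigid-body motion parameters, and one indicator
   regressor per spike frame. Estimation uses robust weighted least squares:
   per-timepoint variances are estimated by pooling squared residuals across
   voxels and timepoints are reweighted by their inverse; two reweighting
   iterations by default (tolerance 1e-6), plain OLS behind a flag. The
   per-block betas are the pattern vectors for decoding; the social contrast
   (mean of all why-face and why-hand block betas minus the mean of all
   how-face and how-hand block betas) is the per-subject feature image for
   score prediction, and the nonsocial contrast is its control twin.

2. **Decoding.** A linear support vector machine with fixed cost `c = 1`
   classifies why vs. how block patterns under leave-two-blocks-out
   cross-validation: every ordered (why block, how block) pair is held out
   once, so `n_why * n_how` folds. The searchlight variant runs this decoder
   in a sphere of radius 4 voxels (257 lattice offsets) around every in-mask
   voxel, writing accuracy to the center; spheres are clipped at mask edges.
   Group-level region discovery tests accuracy > 50% per voxel with a
   one-sample t statistic, controls the familywise error by max-statistic
   sign-flip permutation (5000 flips by default; Bonferroni behind a flag),
   intersects the significant sets across target conditions, and keeps
   6-connected clusters of at least 5 voxels. Cross-sample decoding trains
   on all of one group's block patterns and tests on another's, both
   directions.

3. **Prediction and inference.** A linear nu-SVR (`nu = 0.5`, cost 1)
   predicts a behavioral score from ROI contrast patterns under
   leave-one-participant-out cross-validation; the accuracy statistic is the
   Pearson correlation r between predicted and observed scores, with
   R^2 = r^2. Cross-sample prediction pools several training samples after
   standardizing features (per voxel) and labels within each sample
   separately, then tests on a held-out sample standardized the same way.
   Significance comes from permutation nulls — label shuffles re-run through
   the full cross-validated pipeline, 1000 permutations by default — with
   the decision rule "observed strictly above the null's 95th percentile",
   an add-one p-value `(1 + #{null >= obs}) / (n_perm + 1)`, and
   Benjamini-Hochberg FDR across the family of ROI-wise tests.

## The synthetic-data generator

Because the analysis chain is validated without any data download, the
package ships a forward model that generates multi-subject studies with
exactly the structure the pipeline assumes:

- a block timeline with counterbalanced why/how order within each target
  category and fixed onsets given a seed;
- BOLD series on a common voxel grid: baseline 100, HRF-convolved block
  responses, i.i.d. Gaussian noise (optional AR(1) and polynomial drift);
- a why-minus-how multivoxel pattern planted in named regions. Each
  subject's pattern is `shared_fraction` times a group-level pattern plus
  `1 - shared_fraction` times a subject-specific pattern, re-normalized to
  unit length — this is what makes cross-sample transfer a falsifiable
  claim: with `shared_fraction = 0` nothing can transfer;
- optionally, a linear encoding of one behavioral score: a *zero-mean*
  unit-norm pattern in a designated region scaled by
  `score_encoding_gain * z(score)`, riding on the why-minus-how modulation
  of the social blocks only. Zero-mean means the encoding lives in pattern
  orientation, not regional mean activation, so univariate ROI means stay
  uninformative while the multivariate regression succeeds; social-only
  means the nonsocial contrast stays uninformative, mirroring the
  domain-specificity controls;
- behavioral tables through a Gaussian copula: network size with a
  negative-binomial margin (mean 16.68, SD 10.23), AQ (15.55 +/- 2.73) with
  a target AQ-network-size correlation of 0.16 (a near-zero association),
  IQ (108 +/- 10) independent of both, and autism-severity scores for the
  ASD group;
- motion traces as slow random walks with optional step-displacement spikes.

Everything is seeded hierarchically (study seed, derived per-subject seeds),
and identical seeds give bit-identical output.

### What the generator does and does not emulate

It reproduces the *statistical* structure downstream stages rely on:
block-locked multivoxel effects, partial sharing across subjects, a linear
pattern encoding of a score, heteroscedastic frames, drifts, motion spikes.
It does not emulate spatial autocorrelation, vascular or physiological
noise, EPI distortion, or any spatial preprocessing — data are generated
directly on the analysis grid, because spatial preprocessing is outside the
package's scope. Passing tests therefore validate the estimators and their
calibration under the stated assumptions, not the behavior of the chain on
raw scanner data.

### Calibration of the planted effect sizes

The generative gains are not physical units; they were fixed once from
pilot simulations and are not study parameters to tune per analysis:

- `condition_effect_gain = 0.3` (with unit-norm region patterns and
  `noise_sd = 1`) puts ROI-wise decoding accuracy near 74% for a
  125-voxel region at 12 subjects — inside the 60-82% range typical of
  published ROI decoding of this task. Gains of 1-1.5 are used where the
  tests need near-ceiling signal (region recovery, cross-sample transfer).
- `score_encoding_gain = 0.08` gives leave-one-participant-out prediction
  accuracies of r = 0.5-0.8 at n = 50 — the magnitude regime of published
  individual-difference predictions — with near-complete power against a
  200-permutation null.

## Numerical choices

- **SVM/SVR solver.** Both decoders run on a compiled sequential minimal
  optimization solver (maximal-violating-pair working-set selection,
  KKT tolerance 1e-6 for classification, 1e-8 for regression) operating on
  precomputed Gram matrices, so cross-validation folds, searchlight spheres
  and label permutations reuse one kernel. The solver is validated in the
  test suite against libsvm (via e1071): dual objectives agree to ~1e-5 and
  held-out classifications agree exactly on hundreds of random problems.
  Patterns enter the decoder as estimated — no feature scaling — unless the
  within-fold standardization flag is set. Note that a linear SVM with a
  fixed finite cost is not exactly invariant to global feature rescaling;
  with the margins produced by beta patterns the cross-validated accuracy
  is empirically invariant (tested), and translation invariance is exact.
- **Drift basis.** The 1/100 Hz high-pass is implemented as
  `floor(2 * T / 100)` discrete-cosine regressors inside the GLM rather
  than as a filter applied to the data, keeping estimation a single
  weighted least-squares problem.
- **Robust weights.** Per-timepoint variances are pooled across voxels
  (the spatial mean of squared residuals); weights are normalized to mean
  1. Two iterations suffice because the weight map is essentially
  converged after one update on simulated data.
- **Ties and degeneracies.** Decoding of an exactly-zero decision value
  classifies as "why" (deterministic); constant-feature pattern sets warn
  and still return an accuracy; a contrast on a design lacking the
  nonsocial condition raises an explicit unavailable-condition error; an
  empty surviving-voxel set in region discovery returns an empty ROI set
  with a warning rather than an error.
- **Cluster handling.** 6-connectivity; ROIs are named by their peak
  coordinates, ordered by peak mean accuracy with lexicographic
  tie-breaking.

## Design choices where the convention was open

- **Familywise correction for the searchlight group test.** Parametric
  random-field FWE is out of scope; the package uses max-statistic
  sign-flip permutation on the per-subject accuracy deviations from 50%,
  which is exact under sign symmetry of the null, with Bonferroni as a
  flagged alternative. Accuracies enter the t statistic untransformed.
- **Fold scheme.** "Repeatedly hold out one block per class" is resolved
  as the exhaustive enumeration of all why-by-how pairs: deterministic,
  unbiased, and at most 36 folds for the designs considered.
- **nu.** Only the cost parameter is conventionally printed for this kind
  of analysis; `nu = 0.5` is the common library default and is exposed in
  the configuration.
- **Per-sample standardization axis.** Features are z-scored per voxel
  column across a sample's subjects, labels across subjects; both are
  configurable.
- **DVARS spike rule.** Raw (not percent-change) DVARS, thresholded per
  run at mean + 2.5 SD.
- **d' correction.** The log-linear (add 0.5 / add 1) rule keeps perfect
  hit and false-alarm rates finite.
- **Motion-outlier clustering.** DBSCAN on the per-subject (FD p50, FD
  p95) points with `min_pts = 4` and `eps` = 5 times the median
  nearest-neighbor distance. A tighter data-driven radius (e.g. 1.5 times
  the median NN distance) leaves too few core points at cohort sizes of
  10-60 subjects and flags most of a well-behaved sample; the multiplier
  of 5 keeps clean cohorts intact while isolating movers an order of
  magnitude away. Both parameters are configurable.
- **Block regressors are unmodulated boxcars** (no reaction-time
  parametric modulation): nothing in the analysis consumes trial-level
  modulation, and the decoders operate on block-level estimates.
- **Label-flip symmetry.** A consistent relabeling of all blocks retrains
  an exactly mirrored classifier, so cross-validated accuracy is invariant
  (verified to machine precision in the tests); only flipping the
  *evaluation* labels maps accuracy a to 100 - a. The test suite asserts
  both properties.

## Problem sizes used in the validation suite

The test suite and the acceptance script run entirely on simulated data at
sizes chosen to make the Monte-Carlo error small relative to each
tolerance: 150 signal-free studies of 12 subjects for the chance-level
calibration (50 +/- 1%); 200 studies of 30 subjects with 200-permutation
nulls for the type-I error of the 95th-percentile rule; one 20-subject
study on a 24^3 grid (radius-4 searchlight, 1000 sign flips) plus 20 null
studies on a 14^3 grid for region recovery and familywise control; 20
seeds at n = 50 per condition for prediction power and the two specificity
controls; and 10 subjects per group for cross-sample transfer at
`shared_fraction` 1 versus 0.

## Known limitations

- Generated data have no spatial noise correlation, so searchlight maps
  are rougher than on real data and cluster extents transfer only
  qualitatively.
- The permutation engine assumes exchangeability of block labels within
  subject (decoding) and of subject-score pairings (prediction); designs
  with strong serial dependence between blocks would violate it.
- The robust-WLS variance model is per-timepoint only; it does not model
  voxel-specific heteroscedasticity.
- Region discovery assumes the accuracy deviation from 50% is sign-
  symmetric under the null; heavily imbalanced designs would need a
  label-permutation null instead.
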