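# blockmvpa

Multivariate pattern analysis and individual-difference prediction for
block-design fMRI.

## The scientific problem

Block-design "why/how" paradigms contrast social inference (judging *why* a
person is doing something — their intentions and feelings) with factual
perception (judging *how* they are doing it) on identical stimuli. Two
questions drive the analysis of such data:

1. **Where is social inference decodable?** Multivoxel activation patterns
   are classified (why vs. how) with a linear support vector machine, both
   in a searchlight swept across the brain and within regions of interest,
   and region discovery is controlled for familywise error at the group
   level.
2. **Do those patterns predict who you are outside the scanner?** A linear
   ν-support-vector regression, trained under leave-one-participant-out
   cross-validation on ROI contrast patterns, predicts individual-difference
   scores (social network size, autism-trait questionnaires, symptom
   severity), with significance from permutation nulls and FDR control
   across regions — including cross-sample generalization, where a model
   trained on pooled neurotypical samples is tested on a clinical group.

The core statistics, in the field's standard notation:

- decoding accuracy: mean % of held-out blocks classified correctly under
  leave-two-blocks-out CV (one why and one how block per fold; all
  `n_why × n_how` pairs), chance = 50%;
- prediction accuracy: Pearson `r` between LOPO-predicted and observed
  scores, `R² = r²`;
- inference: empirical nulls from label permutations re-run through the full
  cross-validated pipeline; one-sided `p = (1 + #{null ≥ obs})/(n_perm + 1)`;
  significant iff the observed statistic exceeds the null's 95th percentile;
  Benjamini–Hochberg FDR across ROIs;
- GLM: one regressor per task block (double-gamma HRF), cosine high-pass at
  1/100 Hz, motion and spike nuisance regressors, robust weighted
  least-squares estimation.

Everything is validated end to end on a built-in synthetic-data generator
that plants known multivoxel condition effects and score encodings, so the
whole chain runs and is testable without any data download.

## Worked example

```r
library(blockmvpa)

# a discovery-sample style task: 4 blocks/condition, 8 stimuli/block
design <- make_block_design(4, 8, tr = 1)

# ground truth: one planted region carrying a why-vs-how pattern and a
# social-network-size encoding
dims  <- c(10, 10, 10)
truth <- make_ground_truth(
  dim = dims,
  regions = list(pSTS = region_box(dims, c(5, 5, 5), 2)),
  condition_effect_gain = 0.3,
  score_encoding_gain = 0.08,
  noise_sd = 1, seed = 7)

study <- simulate_study(30, design, truth, seed = 7)

# GLM per subject -> block patterns and social contrast images
fits <- lapply(study$subjects, function(s)
  fit_glm(s, build_design_matrix(design, motion = s$motion)))
contrasts <- t(sapply(fits, contrast_image, "social"))

# ROI decoding of why vs. how
acc <- sapply(fits, function(f)
  decode_patterns(block_patterns(f, voxels = truth$regions$pSTS)))
mean(acc)
#> [1] 74.42708

# LOPO nu-SVR prediction of network size from the ROI contrast pattern
feats  <- contrasts[, truth$regions$pSTS]
scores <- study$behavior$sni_size
res <- test_prediction(lopo_svr(feats, scores), feats, scores,
                       n_perm = 1000, seed = 7)
res
#> Cross-validated score prediction (lopo, 30 folds)
#>   accuracy r = 0.706, R^2 = 0.499
#>   permutation p = 0.000999 (null 5th/95th: -0.657 / 0.111) *
```

The planted region decodes the inference condition at ~74% (chance 50%), and
the score encoding is recovered with `r = 0.71`, far above the permutation
null's 95th percentile (0.11), so the prediction is significant at
`p ≈ 0.001` — the same decision rule applied to every ROI-wise test.

A full pipeline run (simulate → QC → GLM → searchlight → ROI discovery →
prediction → inference → report) is one call:

```r
state <- run_pipeline(default_config(), out_dir = "out")
state$report   # ROI x decoding accuracy, prediction r, null percentiles, p
```

or, from a shell, `exec/blockmvpa report --seed 1 --out out`.

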