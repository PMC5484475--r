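---
title: "Molecular grading of breast tumors from antibody microarray profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular grading of breast tumors from antibody microarray profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nottingham histological grade is a standard prognostic factor in breast
cancer, but it is assigned by visual microscopy and the intermediate grade 2
— 30–60% of diagnoses — is a heterogeneous catch-all that is poorly
informative for treatment decisions. `abgrade` implements an analysis
pipeline for recombinant antibody (scFv) microarray profiling of tumor
tissue that (i) tests whether the immunoproteomic profile separates grade 1
from grade 3 tumors, (ii) condenses the antibody panel into a small
biomarker signature, and (iii) uses grade 1 and grade 3 tumors as anchors to
re-classify individual grade 2 tumors as grade-1-like, grade-3-like, or
indeterminate.

The expected data are background-subtracted fluorescence intensities for
roughly 293 antibody clones spotted in triplicate, measured over a cohort of
a few dozen tumors, together with PBS negative-control spots per array and a
per-sample grade annotation.

```{r}
library(abgrade)
sim <- generate_dataset(synthetic_config(seed = 1))
pp <- preprocess(sim$raw)
pp
```

## Preprocessing model

Stages run in a fixed order that mirrors how such arrays are processed:

1. **Replicate aggregation (15% CV rule).** Each (sample, antibody) cell is
   the mean of its three replicate spots; when the triplicate coefficient of
   variation (sample SD / mean) exceeds `cv_threshold = 0.15`, the replicate
   farthest from the median is dropped and the remaining pair averaged. A
   non-positive triplicate mean makes the CV undefined and is treated as
   exceeding the threshold. Pairs are averaged as-is; the pair CV is kept in
   the QC report so wild pairs remain visible.
2. **Limit-of-detection filter.** LOD = mean(PBS) + 2·SD(PBS), per sample
   when every array carries its own PBS spots (the preferred mode),
   otherwise pooled. An antibody is discarded when its aggregated intensity
   falls below the LOD in *strictly more than* `lod_sample_fraction = 0.70`
   of the samples. When no PBS spots exist the filter is skipped with a
   warning rather than guessed.
3. **Outlier flagging.** PCA on log2 aggregated intensities; a sample whose
   distance from the centroid in the first three components exceeds
   `outlier_z = 3` robust SDs (median/MAD) is *flagged*. Removal is never
   automatic — the analyst confirms with `drop_samples=` — because outlier
   judgement on arrays is ultimately visual and silent sample loss is worse
   than a flagged one.
4. **Semiglobal normalization.** Analytes are ranked by across-sample CV on
   linear intensities and the lowest `ref_fraction = 0.15` (rounded
   half-up, so 290 retained analytes give 44 references) form the reference
   set. Each sample's factor is `N_i = S_i / mu`, with `S_i` the sum of its
   reference intensities and `mu` the cohort mean of the `S_i`; all of
   sample *i*'s values are divided by `N_i`. By construction `mean(N) = 1`
   and every reference sum equals `mu` afterwards.
5. **log2 transform.** Values at or below 0 (possible after background
   subtraction) are floored at `log_floor = 1` and counted.

Two properties of the normalization are worth keeping in mind. First, a
multiplicative distortion of one array is absorbed *exactly* by its own
factor; only the common rescale of `mu` remains, so between-sample structure
is fully cleaned. Second — a genuine limitation — ranking analytes by CV on
scale-contaminated data slightly favors analytes whose biological variation
happens to cancel the array scale, so the factors under-correct on average:
on synthetic data a residual correlation of roughly 0.2–0.5 between true
scale factors and normalized sample means remains, against ~0.95 before
normalization. This bias is intrinsic to CV-ranked reference selection at
cohort sizes like these, not an implementation artifact; the test suite pins
the before/after contrast rather than pretending the removal is perfect.

## Classification model

Grades are compared pairwise with a linear soft-margin SVM (cost `C = 1`,
no feature standardization — normalized log2 intensities enter directly;
a `standardize` switch exists). Training goes through libsvm with the
termination tolerance fixed at 1e-6 so decision values are reproducible;
the primal weights and bias are extracted so a decision value is the affine
score `w·x + b`, with grade 1 mapped to the positive side throughout the
package. Performance is always assessed by leave-one-out cross-validation —
each sample is scored by a model that never saw it — and summarized as
ROC AUC via the Mann–Whitney identity (ties counted ½).

Differential expression per analyte uses the unpaired two-sided rank-sum
test: exact enumeration when the pooled size is at most 12 without ties,
normal approximation with tie and continuity correction otherwise. The
unpaired test is the deliberate choice for independent grade groups of
unequal size (a paired signed-rank mode exists for paired designs). Fold
changes are ratios of linear-scale group means; q-values are
Benjamini–Hochberg.

## Signature discovery

`backward_eliminate()` performs SVM recursive feature elimination: train on
all remaining features, remove the feature with the smallest squared weight
(ties break to the lexicographically first identifier so runs are
deterministic), repeat until `panel_size = 20` features remain. One feature
is removed per step; no chunking. The classification quality along the path
is tracked by the Kullback–Leibler error of LOOCV decision values: decisions
are mapped through the logistic sigmoid and scored with mean cross-entropy
against the 0/1 labels, probabilities clipped to [1e-12, 1-1e-12]. The exact
form of this error is a package definition (the literature it descends from
does not fix normalization or log base); all tests are written against this
definition. The curve is diagnostic: the signature size stays fixed at 20
rather than being read off the curve's minimum. An alternative criterion
(`criterion = "greedy_kl"`, remove the feature whose removal minimizes the
training K-L error) is provided for sensitivity analysis at O(p) fits per
step.

Across resampling runs, `consensus_signature()` ranks analytes by how often
they appear in the condensed signatures. Ties break by the smaller mean
removal rank *counted from the most-important end* (survivors rank 0, the
last-eliminated feature rank 1, and so on) — i.e. the analyte that survived
longer on average — then by identifier.

## The three grading models

* **Model 1 (frozen grey zone).** One SVM is trained on all grade 1 + 3
  anchors restricted to the 20-plex signature and frozen; grade 2 tumors
  with decision value ≥ 0.5 are called grade-1-like, ≤ −0.5 grade-3-like,
  and the rest stay indeterminate (boundaries inclusive toward the
  anchors). Anchors score perfectly against themselves here, but that
  self-classification is biased — which motivates the bootstrap models.
* **Model 2 (bootstrap, per-iteration signatures).** Each of
  `n_iter = 100` iterations draws the anchor groups with replacement at
  their original sizes, runs backward elimination on the draw, trains a
  frozen SVM, and classifies every grade 2 tumor plus the out-of-bag
  anchors by decision-value *sign* (the ±0.5 grey zone belongs to model 1
  only; per-iteration calls are binary tallies). A sample's score is the
  signed percentage 100·(grade-1 calls − grade-3 calls)/times tested, in
  −100..100; |score| < `tally_cut = 70` stays indeterminate. The percentage
  scale puts anchors — tested only out-of-bag, about 37 of 100 iterations
  in expectation — on the same axis as grade 2 tumors tested every
  iteration.
* **Model 3 (bootstrap, fixed consensus panel).** As model 2, but every
  iteration uses one fixed signature, by default the consensus panel of a
  completed model-2 run, removing the iteration-to-iteration signature
  churn that sample selection causes in small cohorts.

Randomness is governed by one master seed; each iteration reseeds with a
value derived deterministically from (seed, iteration), so increasing
`n_iter` extends a run without reshuffling earlier draws, and outcomes are
bit-identical across repeats.

## The synthetic generator

`generate_dataset()` produces replicate-level raw data with the structure
the pipeline assumes, plus ground truth for every planted feature. Defaults
describe the cohort the pipeline targets: 9/17/24 samples of grade 1/2/3,
293 antibodies in triplicate, 20 informative analytes shifted by
`delta = 1.5` log2 units between grade 1 and grade 3 (90% up in grade 3,
10% up in grade 1, mirroring the minority-direction markers seen on such
arrays), replicate CV 7%, log-normal per-array scale factors (SD 0.2 on the
log scale), 8 PBS spots per array at mean 30 SD 10 (nominal LOD 50), three
analytes planted below the LOD, and a grade 2 cohort mixed from
grade-1-like / grade-3-like / intermediate profiles at weights
(0.2, 0.6, 0.2) — intermediates sit halfway between the anchor means.
Baseline log2 means are Normal(10, 1.5) truncated below at 7 (about 2.5
log2 units above the nominal LOD): printed arrays target detectable
analytes, and without the truncation a sizeable fraction of seeds would
plant an accidental extra below-LOD analyte, making "the filter removes
exactly what was planted" untestable. Replicate noise is multiplicative
log-normal so the CV is scale-free, matching a fluorescence error model.

What the generator does *not* emulate: spatial slide artifacts, antibody
cross-reactivity, batch structure beyond one scale factor per array,
missing clinical covariates, or realistic correlation between analytes
(each analyte's biological variation is independent). Passing tests
therefore demonstrate that the pipeline recovers planted structure under
its own assumptions — not that the assay itself has any particular
accuracy on real tissue.

## Numerical choices and test problem sizes

* Rounding of the reference fraction is half-up (290 → 44).
* The LOD comparison and the >70% rule are strict inequalities.
* RFE tie-breaks and the solver tolerance (1e-6) are fixed for determinism.
* Decision values of exactly 0 in a bootstrap iteration count as neither a
  grade-1 nor a grade-3 call (they still count as tested).
* Null calibration in the test suite uses 2000 null analytes for the
  rank-sum type-I error, and 10 generator seeds for the no-effect LOOCV
  AUC. At 9 + 24 samples the null AUC has a sampling SD of about 0.11, so
  the calibration window [0.3, 0.7] is checked on the AUC aggregated over
  the replication, with the spread reported by the test.
* Parameter-recovery checks run 10 seeds at `delta = 3` for signature
  recovery, and the grade-2 mixture recovery uses 40 bootstrap iterations
  for model 2 (per-iteration elimination is the expensive path: ~270 SVM
  fits per iteration) and 100 for model 3; these sizes keep the default
  suite in the minutes range while leaving every statistical conclusion
  unchanged.

## Known limitations

* The CV-ranked reference selection bias described above.
* Fold-change columns are plain ratios of linear group means; published
  tables from comparable assays sometimes print fold-change-like columns on
  other, undocumented scales, and no attempt is made to reproduce those.
* The K-L error form is a package definition (see above).
* With anchors of 9 and 24 samples, single-seed estimates of AUC or of the
  grade-2 split are noisy; conclusions should rest on the bootstrap models
  and on replication over seeds, which is how the test suite treats them.
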