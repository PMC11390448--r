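---
title: "Weakly supervised multi-instance detection of pancreatic tumors: methods and design"
author: "milct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised multi-instance detection of pancreatic tumors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milct)
```

## The problem

Pancreatic ductal adenocarcinoma is usually detected late: the organ is
small, sits deep in the retroperitoneum, appears on only a minority of a CT
study's axial slices, and early lesions are subtle. Slice-level annotation of
large cohorts is impractical, so the realistic labeling regime is *weak
supervision*: for each patient we know only a binary case/control label,
while the quantity of clinical interest (which slices carry tumor, and
ultimately whether the patient has one) is finer-grained.

`milct` implements a two-stage architecture for this regime. Stage one is
organ localization: an external segmentation model (in practice nnU-Net; in
our tests the phantom's ground-truth masks) supplies a pancreas mask, and the
classifier only ever sees the cropped organ region, which suppresses false
positives from the rest of the abdomen. Stage two is multi-instance learning
(MIL): each patient is a *bag* of 2D axial instances cropped from the organ
region; a patient is positive iff at least one instance contains tumor.
Instance pseudo-labels inside positive bags are inferred by K-means
clustering of instance features, a softmax head is trained on the
pseudo-labeled instances, and a small neural network aggregates the bag's
instance probabilities into one patient-level cancer probability.

## The phantom world

Clinical CT cohorts of this kind are private, so the package ships a seeded
phantom generator whose statistical structure matches what the pipeline
assumes, making every downstream stage testable offline.

Each study is a `grid_shape` volume (default 64 x 64 x 32 voxels) with
anisotropic spacing (default 1 x 1 x 2.5 mm — 2.5 mm is a standard
pancreas-protocol axial cut). The organ is an axis-aligned ellipsoid with
semi-axes `organ_radius * (1, 0.8, 0.5)` (default 20 mm, flattened axially so
the organ spans roughly a quarter of the slices, mirroring the clinical
"20-60 of ~131 slices" situation). A case carries one spherical lesion
(default radius 6 mm) placed uniformly inside the organ, shrunk so the
sphere always fits: the tumor mask is a strict subset of the organ mask and
`label = 1` iff the tumor mask is non-empty. Intensities are HU-like:
background -80, organ 80, tumor 40 — portal-venous-phase adenocarcinoma is
hypodense relative to enhancing parenchyma — with additive Gaussian noise
(default sd 10 HU, typical abdominal CT noise). With `noise_sd = 0` every
painted voxel is exact, which gives the tests a voxel-threshold oracle:
tumor and organ voxels are perfectly separable by one intensity cut.

Deliberately *not* emulated: real anatomy (neighboring organs, ducts,
vessels), scanner artifacts, contrast-phase variation, irregular tumor
margins, and segmentation-mask errors beyond what the crop margin absorbs. A
green test therefore establishes that the pipeline's machinery — cropping,
pseudo-labeling, classification, aggregation, evaluation — behaves as
specified on data with the assumed structure; it says nothing about clinical
performance.

## Preprocessing

* **Series screening** (`screen_series()`) applies four exclusion rules in a
  fixed priority order, first failure wins: gaps in the slice index sequence,
  in-plane pixel-spacing drift beyond 1e-3 mm, mixed orientation tags, and a
  quality/segmentation-failure flag. These mirror the usual reasons clinical
  series are dropped before analysis.
* **Resampling** (`resample_image()`, `resample_mask()`) converts
  heterogeneous spacing to a homogeneous target: separable third-order
  (natural cubic) spline interpolation for images, nearest-neighbor for
  masks (no new label values can appear). The output shape convention is
  `round(shape * old_spacing / new_spacing)`; the identity case is exact.
  One caveat: a there-and-back resample restores the original shape only
  when `shape * old / new` is near-integral (e.g. 64 slices at 1 mm to
  2.5 mm gives `round(25.6) = 26`, and back 65); the spacings used by the
  pipeline are ratio-compatible.
* **Target spacing.** The pipeline default resamples to the cohort's median
  (= native) spacing, the same convention nnU-Net uses, rather than to
  isotropic 1 mm. Upsampling z 2.5 mm to 1 mm manufactures interpolated
  boundary slices whose spline-interpolated image content and
  nearest-neighbor mask disagree; at slice-level granularity those
  manufactured slices are ambiguous by construction and measurably degrade
  pseudo-label recovery.
* **Normalization** (`normalize_global()`) is the affine map
  `(x - mean)/sd` with statistics frozen from the training cohort's organ
  voxels and reused at validation/test time.

## Instance extraction

`mask_bounding_box()` computes the tight half-open box around the organ
mask, dilates it by `margin_mm` (default 5 mm, converted per axis and
clipped) to cushion imperfect masks, and `build_instances()` crops one
in-plane box — shared across the patient's slices so instances align — for
every axial slice on which the organ appears, rescaling each crop
bilinearly to 64 x 64. One instance per organ slice; tumor voxels always lie
inside the crop because tumor ⊆ organ ⊆ box.

## Features and pseudo-labels

**Extractor.** The reference architecture uses an ImageNet-pretrained
ResNet50 with features read at an average-pooling layer. No deep-learning
framework (nor pretrained weights) is available in this environment, and
hand-rolling convolutional backpropagation would dwarf the part of the
method that matters here, so the default extractor is a *fixed-weight*
random-feature CNN: three 3x3-conv/ReLU/2x2-average-pool blocks with
He-initialized weights drawn once from a seed, then a 4x4 average pool
(matching the head's pooling) and flattening — 32 features per instance.
Random convolutional features preserve exactly the kind of local contrast
information the clustering needs, are deterministic, and cannot leak labels.
A plain block-average-pooling extractor (`extractor_pool()`) is kept as the
transparent baseline, and the interface is pluggable for anyone with a real
backbone.

**Standardization.** Weak supervision supplies one trustworthy reference
population: the instances of negative bags, all tumor-free. All features are
standardized per dimension by the training negatives' mean and sd
(`feature_stats()` / `standardize_features()`). This matters: raw feature
variance is dominated by organ geometry (cross-section area waxes and wanes
along z), and K-means on raw features splits bags by geometry, not lesion —
with the perverse effect that the "far from negative centroid" orientation
rule picks the *end-slice* cluster and inverts the labels. In standardized
space, distance from the negative population is a diagonal Mahalanobis
distance: directions in which healthy slices naturally vary are shrunk,
lesion contrast dominates.

**Abnormality score.** `abnormality_score()` scores each instance by its
Euclidean distance to the nearest negative-bag instance, in units of the
negative cohort's own cross-patient nearest-neighbor distance (computed
leave-own-patient-out so within-patient slice similarity cannot deflate the
scale), saturated at `cap = 5`. Healthy slices — which have close analogues
in other patients' tumor-free bags — score near 1; lesion slices score high.

**Clustering and orientation.** Per positive bag (the default; pooled
clustering across bags is a config switch), K-means with k = 2 partitions
`log1p(score)` — the log compresses the heavy lesion tail so the
sum-of-squares split lands in the healthy/lesion gap rather than inside the
lesion tail — and the cluster with the larger median score is labeled 1.
Two guard rails: a pseudo-positive whose score does not exceed the 97.5th
percentile of the negatives' own scores is re-labeled 0 (without this gate,
ambiguous bags flood the classifier with mislabeled healthy slices and
control patients inherit high probabilities), and every positive bag keeps
at least one positive instance (its most abnormal one), honoring the MIL
axiom. Negative bags never enter clustering; their instances are labeled 0
directly. Single-instance positive bags are labeled 1 without clustering.

The centroid-based orientation rule (far cluster from the negative-instance
centroid is positive) is retained verbatim as `assign_pseudo_labels()` and
as `pseudo_label_method = "centroid"`; as noted above it is unreliable
whenever organ geometry, not lesion contrast, dominates the feature
variance, which is why it is not the default.

**K-means.** `kmeans_partition()` is k-means++ seeding with 10 restarts,
each optimized by the Hartigan-Wong exchange pass (`stats::kmeans`), with an
internal Lloyd loop (centroid-movement tolerance 1e-4) as the
degenerate-input fallback. Hartigan-Wong is used deliberately: on small
instance sets there exist configurations whose global optimum no Lloyd run
from data-point seedings can reach, while exchange moves find it; the test
suite checks the attained within-cluster SS against an exhaustive-partition
oracle on hundreds of random small instances.

## Instance classifier

The head follows the reference architecture: the pooled features, a dense
layer of 256 units (ReLU), dropout 0.3 between it and the output, and a
2-unit softmax. It is trained with full-batch Adam (300 epochs, lr 5e-3,
weight decay 1e-4) by a small built-in network implementation; training is
seeded and bit-reproducible. Two pipeline choices support generalization
from one modest cohort:

* **Dihedral augmentation** (`augment = TRUE`): each training instance also
  appears under the 8 symmetries of the square. The features are
  location-coded, lesions occur anywhere in the organ, and one cohort's
  lesion positions under-cover the space.
* **Abnormality input**: the classifier input is the standardized feature
  vector plus two views of the abnormality score (capped linear and
  uncapped log). The capped view separates healthy from lesion robustly;
  the uncapped view keeps gradation among clear lesions — with only the
  capped value, every unambiguous training lesion collapses onto a single
  input value and the head has nothing to extrapolate from.

## Aggregation

A bag's variable-length list of instance probabilities is encoded as a
10-bin normalized histogram on [0, 1] (right-closed last bin) — invariant to
instance order, instance count, and duplication; mean/max and top-k
summaries are available behind `aggregator_config(summary = ...)`. A
one-hidden-layer perceptron with 18 units and a logistic output maps the
summary to the patient probability; when a validation split is available the
epoch minimizing validation loss supplies the returned weights ("parameters
fixed by the validation dataset"), and nothing is ever tuned on test data.
The default decision threshold is tau = 0.5.

## Evaluation

Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/n, and the
Mann-Whitney AUC with half-credit for ties (equal to
trapezoidal ROC integration). `delong_ci()` implements the DeLong
placement-value variance `S10/n1 + S01/n0` and the normal-approximation
two-sided CI clipped to [0, 1]; perfectly separated scores give a degenerate
[1, 1] interval, and a Monte-Carlo coverage test (binormal scores, 2000
replicates) checks empirical 95% coverage. An undefined metric (zero
denominator) raises an error, never a silent 0. `dice_score()` is
2|A∩B|/(|A|+|B|) with the both-empty-masks-agree convention (= 1), stated
explicitly because conventions differ. Ties in the cluster-orientation
distance break deterministically (lower cluster index positive) with a
warning.

## End-to-end behavior and limitations

`run_end_to_end()` derives every stage seed from one global seed, splits
patients stratified by label (no patient's instances straddle splits),
freezes normalization and feature statistics on the training split, and
re-running an identical config reproduces the report byte for byte.

```{r example, eval = FALSE}
cfg <- run_config(
  phantom = phantom_config(n_cases = 30, n_controls = 30, seed = 162,
                           noise_sd = 10),
  seed = 62)
report <- run_end_to_end(cfg)
report
```

On the phantom world the pipeline's measured behavior (recomputed by the
test suite and `scripts/acceptance.R`, not asserted from memory) is:
noiseless high-contrast cohorts reach test accuracy 1.0; pseudo-labels
recover ground-truth tumor-slice indicators for well over 95% of
positive-bag instances on noiseless high-contrast cohorts; and
moderate-noise cohorts reach test AUC near 1. Residual cohort-draw variance
remains: across ten independent 30+30 moderate-noise draws, one produced a
test AUC of ~0.85 (a single case bag whose lesion the instance classifier
under-scored, still ranked above most controls). We report this rather than
tune it away; with cohorts of this size, patient-level metrics on a 14-
patient test split are quantized in steps of ~0.07.

Known limitations: the feature extractor is untrained (a real backbone
should improve the moderate-noise regime); the abnormality score's
nearest-neighbor search is O(instances x negatives) and would need indexing
at clinical scale; the aggregator sees only the probability distribution,
not inter-slice spatial structure; and the phantom's simplifications mean
none of the reported numbers transfer to clinical data.
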