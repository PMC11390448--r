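# milct — weakly supervised multi-instance detection of pancreatic tumors in CT

`milct` is an R implementation of a two-stage, weakly supervised pipeline for
detecting pancreatic tumors in volumetric CT when only **patient-level**
labels (case vs. control) are available, while the signal of interest lives
at the **slice** level. It is aimed at methods researchers in medical image
analysis who want a fully seeded, dependency-light testbed for
multi-instance learning (MIL) on organ-cropped CT, plus reusable evaluation
utilities (DeLong confidence intervals, dice overlap).

## The method

Stage 1 (localization) consumes a pancreas segmentation mask — from an
external model such as nnU-Net, or from the built-in phantom's ground truth —
and crops the organ region. Stage 2 (classification) is MIL:

1. **Bags.** Each patient *i* is a bag `X_i = {x_1, …, x_n}` of 2D axial
   instances cropped from the organ region, with bag label
   `Y_i ∈ {0, 1}`; `Y_i = 1` iff at least one instance contains tumor.
2. **Features.** Each instance gets a fixed-length feature vector `f_j`
   from a pluggable extractor (default: a seeded fixed-weight 3-block CNN
   with a 4×4 average-pool readout), standardized against the training
   negative-bag instances.
3. **Pseudo-labels.** Inside each positive bag, K-means (k = 2, k-means++
   seeding, 10 restarts, Hartigan–Wong optimization) partitions the
   instances by an abnormality score — distance to the nearest tumor-free
   instance, normalized by the negatives' own cross-patient scale — and the
   cluster with the larger median score gets `y_j = 1`. Negative-bag
   instances are labeled 0 without clustering.
4. **Instance classifier.** Dense(256, ReLU) → dropout(0.3) → dense(2,
   softmax), trained on the pseudo-labeled instances with Adam; output
   `p_j = P(tumor | x_j)`.
5. **Aggregation.** The bag's probabilities are encoded as a 10-bin
   histogram and a one-hidden-layer perceptron (18 units, logistic output)
   produces the patient-level cancer probability, thresholded at τ = 0.5.

Evaluation reports sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
accuracy, the Mann–Whitney AUC (ties count ½), the DeLong variance
`S₁₀/n₁ + S₀₁/n₀` with its 95 % normal-approximation CI, and the dice
coefficient `2|A∩B|/(|A|+|B|)` for mask overlap.

Because clinical cohorts of this kind are private, the package ships a
seeded phantom generator (ellipsoidal organ occupying a minority of axial
slices, spherical hypodense lesion for cases, anisotropic spacing, additive
Gaussian noise, minimal NIfTI-1 I/O) so that the entire pipeline is testable
offline. See `vignettes/milct-methods.Rmd` for the full methods account.

## Worked example

```r
library(milct)

cfg <- run_config(
  phantom = phantom_config(n_cases = 30, n_controls = 30, seed = 162,
                           noise_sd = 10),
  seed = 62)
report <- run_end_to_end(cfg)
report
#> <mil_report> 60 patients (30 cases / 30 controls), 480 instances
#>   test: n=14  accuracy 1.000  sensitivity 1.000  specificity 1.000  AUC 1.000
#>   DeLong 95% CI: 1.000-1.000

head(report$test_predictions[order(-report$test_predictions$probability), ], 4)
#>   patient_id label probability decision
#> 2   case_003     1   0.9999623        1
#> 3   case_005     1   0.9998254        1
#> 6   case_028     1   0.9998080        1
#> 1   case_002     1   0.9997861        1
```

The report says: of 60 simulated patients, the held-out test split (14
patients, untouched during training and model selection) was classified
perfectly at τ = 0.5 on this cohort draw, and the DeLong interval is
degenerate because the score distributions are fully separated. Re-running
the same config reproduces the report byte for byte. (Across independent
cohort draws at this noise level the test AUC is typically 0.94–1.0; the
vignette discusses the variance honestly.)

Single phantoms round-trip through NIfTI:

```r
v <- generate_patient(phantom_config(noise_sd = 0), label = 1, seed = 5)
v
#> <phantom_volume>   dims 64x64x32  spacing 1x1x2.5 mm  label 1
#>   organ voxels: 5401 on 8 axial slices; tumor voxels: 365
paths <- write_study(v, tempfile())
dice_score(read_study(dirname(paths[1]))$organ_mask, v$organ_mask)
#> [1] 1
```

A small CLI lives at `inst/cli/milct`
(`milct simulate|run|evaluate ...`).

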