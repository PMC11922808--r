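---
title: "Methods: transfer learning for single-image 3D fMRI classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transfer learning for single-image 3D fMRI classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Deep-learning classifiers for neurodegenerative disease need far more
training data than a typical clinical site can supply. One remedy is
transfer learning: pre-train a network on a large cohort from a related
task (here: an autism-spectrum classification problem with hundreds of
participants), then fine-tune all of its weights on the small cohort of
interest (a few dozen Alzheimer's patients and controls), evaluating the
small cohort by leave-one-out cross-validation (LOOCV) so that no
precious sample is wasted on a held-out split. The input is deliberately
clinician-friendly: a *single* multi-channel 3D volume per participant —
ICA-derived brain-network spatial maps extracted from one resting-state
fMRI — rather than 4D time series or 2D slices.

`fmritransfer` implements that protocol end to end as a tested,
reusable R package: a synthetic spatial-map phantom generator, volume
I/O and transforms, a small 3D convolutional network with its own
optimizer, source training with early stopping, the two-arm LOOCV
transfer protocol, the metric suite, and a one-call pipeline.

## The model

The classifier is a deliberately small, C3D-style 3D CNN. For the
full-size 61×61×61 input with 8 channels:

| layer | in → out channels | kernel | stride | per-axis size |
|---|---|---|---|---|
| Conv3D + LeakyReLU | 8 → 16 | 6³ | 1 | 61 → 56 |
| MaxPool3D | — | 6³ | 2 | 56 → 26 |
| BatchNorm3D | 16 | — | — | 26 |
| Conv3D + LeakyReLU | 16 → 32 | 6³ | 1 | 26 → 21 |
| MaxPool3D | — | 6³ | 2 | 21 → 8 |
| BatchNorm3D | 32 | — | — | 8 |
| Conv3D + LeakyReLU | 32 → 64 | 4³ | 1 | 8 → 5 |
| MaxPool3D | — | 4³ | 2 | 5 → 1 |
| BatchNorm3D | 64 | — | — | 1 |
| Flatten → Linear + LeakyReLU | 64 → 20 | — | — | — |
| BatchNorm1D, Dropout(0.5) | 20 | — | — | — |
| Linear → Sigmoid | 20 → 1 | — | — | — |

The flatten length (64 = 64 channels × 1³ voxels) is part of the
architecture contract: `cnn_config()` performs the complete shape
arithmetic at construction and *errors* on any configuration whose
convolution/pooling trace collapses or whose flatten length disagrees
with an `expected_flatten`, rather than silently padding. The default
network has 271,009 trainable parameters (verified in the tests against
an independent hand computation).

Training minimizes binary cross-entropy with Adam. The two recipes are:

* **source**: 100 epochs, minibatch 52, random rotation p = 0.5,
  lr = 1e-4, early stopping with patience 15, hold-out 80/10/10 split;
* **fine-tuning**: 300 epochs, full batch (n − 1 = 63 for a 64-person
  cohort), rotation *and* left-right flip p = 0.7, lr = 1e-5, **no**
  early stopping (with a single held-out sample per fold there is no
  validation signal to stop on; the spec type has no patience field).

Because every layer is implemented in the package (conv/pool kernels in
C++ via im2col + BLAS GEMM, batch-norm/linear/dropout in R), the whole
forward–backward path is finite-difference checked in the test suite.

## Decisions the architecture tables leave open

Several details are not fixed by the recipe tables above; the package
resolves each one explicitly and records it in configuration:

* **Normalization "0.5, 0.25"** is read as the center/scale of a
  standard image-normalization transform applied after per-volume
  min–max rescaling to [0, 1]: the output spans exactly [−2, 2], and a
  constant volume maps to −2 everywhere. The statistics are strictly
  per-volume, which is also what makes the LOOCV leakage audit's
  normalization check meaningful.
* **Order of deterministic transforms**: resize (trilinear), then
  normalize. Recorded in the run manifest.
* **Rotation magnitude**: the recipes state only the probability; the
  package draws the angle uniformly from ±15° about one uniformly chosen
  spatial axis, filling exposed corners with the channel's minimum
  (its background value). Small rotations preserve anatomy-like
  structure.
* **Flip axis**: the first spatial axis, the anatomically plausible
  left–right mirror.
* **LeakyReLU slope 0.01** and Kaiming-style seeded initialization;
  batch-norm momentum 0.1. All recorded in `cnn_config()`.
* **Decision threshold** 0.5 on the sigmoid output, ties predicting
  positive (documented in `confusion_from_predictions()`).
* **Split rounding**: hold-out sizes use largest-remainder rounding per
  class (remainder ties broken toward the globally under-filled split),
  which reproduces 420/52/52 for 524 participants at 80/10/10 — making
  the source batch size 52 exactly one validation split.
* **Channels**: the feature-extraction stage of the original protocol
  yields 53 ICA components grouped into 7 network domains, while the
  network's first layer takes 8 channels; the mapping between the two is
  not specified anywhere authoritative. The package treats the channel
  count as configuration (default 8, interpretable as 7 network-domain
  maps plus one whole-brain composite) rather than guessing a packing.
* **"Improvement"** for early stopping means a strictly lower validation
  loss, no minimum delta; the checkpoint kept is always the minimum-loss
  epoch, including its batch-norm running statistics.
* **Incomplete minibatches** are kept, not dropped: small cohorts cannot
  afford discarding samples.
* **Adam constants** beyond the learning rate stay at the conventional
  0.9/0.999/1e-8.

## The LOOCV transfer protocol

`run_loocv()` runs one fold per participant. Every fold (a) initializes
the weights — transfer arm: a bitwise copy of the frozen source
checkpoint; reference arm: a fresh seeded initialization ("the same code
without the source weights") — with *all* layers trainable; (b)
fine-tunes on the other n − 1 participants with augmentation redrawn
every epoch; (c) predicts the held-out participant in eval mode.
Eval-mode prediction uses the accumulated batch-norm running statistics
and disabled dropout, so a batch of one is well defined — the property
LOOCV depends on.

Fold seeds are derived from the protocol seed *and the held-out
participant's id*, so folds are reproducible in isolation and the result
is provably independent of fold execution order (a tested invariant).
Weights are created inside the fold and discarded after it; nothing can
cross fold boundaries. `leakage_audit()` re-checks a finished run from
its provenance: held-out ids absent from their folds' training ids,
per-fold starting-weight checksums matching the arm, and per-volume
normalization. Violations are returned as data, not thrown.

Aggregation pools all held-out predictions into one confusion matrix
(rather than averaging per-fold accuracies) and derives accuracy,
sensitivity, specificity, precision, F1 and the Matthews correlation
coefficient. Zero-denominator metrics are reported as 0 with an explicit
degenerate flag, keeping pooled reports total and auditable. Per-fold
validation curves can be recorded but are deliberately not used for any
decision — with one sample per fold they are mostly superficial. The
comparison report states the between-arm accuracy difference in
percentage points, subtracting the two accuracies as printed at two
decimals, the same arithmetic a reader applies to a results table.

## The synthetic phantom generator

Real cohorts of this kind sit behind data-use agreements, so the package
ships a generator that emulates the *output* of the feature-extraction
stage — not BOLD physics. Each participant volume is a sum of smooth
component blobs (isotropic Gaussians, σ = 2 voxels, peak-normalized,
centers ≥ 4 voxels apart per channel) weighted by per-participant
amplitudes ~ Normal(1, 0.1), plus voxel-wise Gaussian noise. Class
membership adds `effect_size` to the amplitudes of a chosen affected
component subset. A source/target pair shares one atlas and overlaps its
affected sets in exactly `round(shared_fraction × k)` components — the
knob that makes "how related are the two tasks?" an experimental
variable.

Amplitudes are keyed by the within-class participant index, giving a
matched-pairs phantom: with zero effect and zero noise the two classes
are voxel-for-voxel identical, which makes null tests exact. All
randomness flows from the spec seed through named sub-streams (atlas,
amplitudes, noise, affected sets), so cohorts are bitwise reproducible.

What the phantom deliberately does **not** model: hemodynamics, motion
or scanner artifacts, inter-site heterogeneity, spatially structured
noise, or real disease topography. Passing tests therefore demonstrate
that the *protocol* (training, transfer, cross-validation, metrics) is
implemented correctly and behaves as theory predicts on data with known
structure — not that any particular accuracy would be achieved on
clinical data.

## The desk-scale study configuration

`demo_run_config()` fixes the package's end-to-end experiment at a size
a single CPU completes in minutes while preserving every structural
element of the full protocol:

* grids 24³ with 8 channels × 7 components; architecture narrowed
  proportionally (8→8/16/32 channels, kernel 3, pool 2, flatten 32);
* source cohort 80 (40/40) with the 80/10/10 hold-out → 64/8/8;
* target cohort 16 (8/8), `shared_fraction = 1`, 12 affected
  components;
* amplitude effect size 1.0 against amplitude noise 0.1 and voxel noise
  0.5 — separable but not trivially so (source hold-out accuracy lands
  well below 1);
* source: 30 epochs, batch 20, lr 1e-3, patience 15; fine-tuning: 12
  full-batch epochs, lr 1e-4, rotation/flip p = 0.7.

The learning rates and epoch counts are scaled up/down from the
full-size recipes to match the smaller network and tighter compute
budget; they were fixed once when the configuration was designed. At
this scale the transfer arm, which starts from a source model trained on
the identical discriminative structure, classifies the 16-participant
target cohort nearly perfectly, while the cold-start reference arm —
twelve full-batch gradient steps from random weights — stays near
chance: the package-scale rendition of the full-scale contrast between
the two arms. With permuted target labels both arms fall back inside the
binomial 95% band around chance.

## Numerical notes

* Convolutions are exact (valid, stride 1) via im2col + dgemm; pooling
  records argmax indices for the backward pass; both are tested against
  naive loop implementations, and the complete backward pass against
  central finite differences.
* The first layer's input gradient is never computed (nothing consumes
  it) — an optimization with no numerical effect.
* Batch statistics use the biased variance for normalization and the
  unbiased one for the running estimate, the convention eval-mode
  single-sample prediction relies on.
* Probabilities are clamped to [1e-12, 1 − 1e-12] inside the loss;
  non-finite losses abort training with the epoch/batch (or fold)
  coordinates.
* Checkpoints are single RDS files holding config + named arrays +
  metadata; round-trips are bitwise.

## Known limitations

* The phantom's simplicity means transfer benefits appear at much
  smaller sample sizes than they would on real imaging data.
* Only binary classification with a single sigmoid output; no
  multi-class staging.
* No ROC/AUC or calibration analysis (the protocol reports thresholded
  metrics only).
* Exact bitwise reproducibility holds for a fixed BLAS/CPU; across
  different linear-algebra libraries results may differ in the last
  bits, which can flip a prediction sitting exactly at the threshold.
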