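---
title: "Methods: phantom radiographs, knee isolation, and KL-grade classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom radiographs, knee isolation, and KL-grade classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Kellgren–Lawrence (KL) grading scores knee osteoarthritis severity from a
radiograph on an ordinal 0–4 scale, driven chiefly by two cues: narrowing of
the radiolucent joint space between femur and tibia, and marginal
osteophytes. Clinical films are usually *bilateral* — one image containing
both knees, each with its own grade — so an automated grading pipeline must
first isolate each knee, then classify it, without ever letting the two
knees of one patient straddle a train/test boundary.

`kneegrade` implements that pipeline end to end: a phantom-radiograph
generator with known ground truth, the image-processing isolation stage, a
patient-level splitting and augmentation protocol, a transfer-learning
classifier architecture with exact parameter accounting, a compact trainable
profile, evaluation metrics, and classical baselines. Because real clinical
datasets of this kind are typically private, every stage is testable against
synthetic phantoms whose geometry is known exactly.

## The phantom generator

`generate_phantom()` renders one bilateral film: two knees, each a femur
block above a tibia block with intensity ~200 on a ~15 background
(8-bit scale), separated by a joint-space gap whose height is a function of
the KL grade — by default 12 / 12 / 8 / 4 / 1 pixels for grades 0–4 at the
nominal 400 × 600 size. Marginal osteophytes are small bright ellipses at
the joint corners, 0 / 0 / 1 / 2 / 4 per grade. Gaussian noise (sd 5 gray
levels) is added and clipped. Two nuisance features that a real isolation
stage must survive are included: per-image size jitter (±15%) and a
text-like annotation block in the upper-left corner, drawn as 1–2-pixel
strokes the way patient details are printed on films.

Three design rules matter:

* **Grades 0 and 1 are image-identical.** Their gap and osteophyte settings
  are forced equal (the configuration validator rejects anything else), and
  the only thing distinguishing them is a latent *pain* flag that drives the
  label: pain with a normal film is grade 1, no pain is grade 0. This
  encodes the labeling convention of symptomatic cohorts, where "KL-0
  controls" are patients with pain but clean radiographs. Any classifier
  fed pixels alone therefore cannot beat chance on 0-vs-1 — a property the
  test suite verifies with a KS test on per-knee image statistics and, at
  the system level, with a trained model's 0-vs-1 AUC.
* **The annotation block must be removable by morphology.** Strokes are at
  most 2 px wide, thinner than the default 5 × 5 opening kernel, so the
  segmentation mask drops them; after bilinear downscaling to the working
  size they also fall mostly below the Otsu threshold.
* **Truth boxes are exact.** The generator records the bounding box of each
  knee's bone pixels (0-based, half-open), giving the isolation stage an
  objective target (column Jaccard overlap).

What the phantom does *not* emulate: real trabecular texture, exposure
variation, patient positioning and rotation, implants, or soft-tissue
shadows. Passing tests on phantoms demonstrates that the pipeline's logic
is correct and that the grade cues it is supposed to use are sufficient for
recovery — not that any particular accuracy will transfer to clinical data.

The default class mix follows the per-grade composition reported for the
clinical cohort this emulates (counts 18/67/105/126/86 for grades 0–4).
Those published counts sum to 402 rather than the patient total, so they
are used strictly as proportions. Ages are uniform on [40, 80], the
inclusion window of such cohorts.

## Knee isolation

`isolate_knees()` runs, in order: grayscale conversion and resize to
224 × 224 (`standardize_image()`), unsharp-mask sharpening
(`sharpen_image()`, amount 1, σ = 1 px), Otsu binarization
(`otsu_threshold()`), 5 × 5 morphological opening
(`morphological_opening()`), column-projection knee detection
(`detect_knee_columns()`), cropping (`crop_knees()`), and square
zero-padding with normalization to [0, 1] (`pad_and_normalize()`).

Decisions where the procedure was genuinely open:

* **Sharpening position.** Sharpening is applied between standardization
  and thresholding, so the binarization sees the enhanced edges; the
  `crop_from` parameter chooses whether the saved crops come from the
  sharpened or the plain standardized image (default: sharpened).
* **Otsu ties.** The threshold maximizing between-class variance over the
  256-bin histogram, with ties broken toward the smallest maximizer;
  foreground is strictly above the threshold. The implementation is checked
  against an exhaustive 256-candidate search.
* **Opening kernel.** A 5 × 5 box is the default, chosen to remove text
  strokes while leaving bone regions (which are far wider than 5 px)
  intact. Border pixels see background outside the image,
  the convention of standard binary morphology, and the operation is
  verified idempotent and equal to EBImage's opening.
* **Row correction as fallback.** Zeroing rows of identical pixels is a
  repair step for suboptimal segmentations; it is applied to the mask only
  when detection fails on the opened mask, with an optional midline split
  (`midline_fallback`) as a last resort.
* **Detection parameters.** Column runs with positive foreground count are
  merged across gaps narrower than `min_gap = 5` columns and dropped when
  shorter than `min_run = 10`; the two largest-area runs, ordered left to
  right, are the knees.
* **Row cropping.** Knee *detection* is purely column-wise; crops are
  additionally trimmed to the foreground row span ± 2 rows so slices are
  tight around the joint rather than spanning the full image height.
* **Pad then resize.** Crops are zero-padded to a square (extra row/column
  to the bottom/right on odd remainders) *before* the bilinear resize to
  224 × 224, which is the only order that standardizes dimensions without
  distorting the aspect ratio; pixel values are then divided by 255.
* **Coordinates** are 0-based and half-open throughout.

## Splitting and augmentation

`patient_split()` shuffles patients under a seed and assigns
`ceiling(test_frac · n)` of them to the test set — the rounding rule under
which 301 patients at 20% give exactly 61 test patients. Stratification by
each patient's maximum knee grade is on by default and falls back (with a
warning) when any stratum has fewer than two patients. All knees of a
patient stay together.

`build_sets()` reproduces the augment-then-split protocol: every training
slice contributes `copies_per_image` augmented copies (rotation within
±30°, isotropic zoom 0.8–1.2, shifts up to 10% per axis, shear within
±20°, horizontal flips at p = 0.5; bilinear resampling with zero fill),
and the pooled result is split 90/10 into training and validation *at slice
level* — validation therefore comes from the augmented pool, while the test
set is held out before augmentation and never augmented. Slice-level
validation lets augmented copies of one image land on both sides; that is
the protocol being reproduced, and a stricter `val_by_patient = TRUE`
variant is available. The configuration default is 5 augmented copies per
slice; the desk-scale experiment uses 2 to keep CPU training in minutes.

## The classifier and its accounting

`build_model()` assembles: a 3 × 3, stride-1, same-padding convolution with
ReLU adapting the single-channel 224 × 224 slice to 3 channels (30
parameters — the only choice of kernel reproducing that count while
preserving shape), a backbone, a flatten, and a fully connected head
128 / 64 / 16 / 5 with ReLU, L2 weight penalty (λ = 10⁻⁴) and dropout 0.3
after each hidden activation, ending in a 5-way softmax.

Backbones are layer-spec tables built from generic counting rules — dense:
`in·out + out`; convolution: `out_ch·(k_h·k_w·in_ch)` plus `out_ch` if
biased; batch-norm: 4 parameters per channel of which the running
mean/variance pair is counted as **non-trainable**. Under that convention
the canonical DenseNet-121 (7 × 7/2 stem of 64 channels; dense blocks of
6/12/24/16 layers, growth 32, 1 × 1 bottlenecks; 0.5-compression
transitions; final batch-norm) yields exactly 7,037,504 parameters with
83,648 non-trainable, emitting 7 × 7 × 1024 features, and the full model
totals 13,469,571 = 13,385,923 trainable + 83,648 non-trainable. The
registry also provides DenseNet-201, ResNet-50 and MobileNet accounting.
The backbone is never frozen: only batch-norm running statistics are
non-trainable.

No ImageNet weight bundle ships with the package (and none is needed by any
test); `pretrained = TRUE` requires a user-supplied weights file.

## The trainable profile

R has no deep-learning framework in this package's dependency set, so the
training engine is written here: conv / ReLU / average-pool / flatten /
dense / dropout layers with explicit analytic backward passes, softmax
cross-entropy, and Adam. The convolution's im2col/col2im memory movement is
in C++ (the arithmetic is BLAS), and every gradient path is verified
against central finite differences in the test suite — the backward-pass
formulas are exercised rather than hand-trusted.

The trainable `"tiny"` backbone is a compact stack — average-pool (2 × 4),
conv 3→16, average-pool (2 × 2), conv 16→32, average-pool (4 × 2) — ending
at 14 × 14 × 32 and feeding the standard head. Three choices deserve
explanation:

* **A plain conv stack rather than a truncated DenseNet block.** Batch
  normalization trained from scratch on 8–16-sample CPU batches is
  unstable, and dense connectivity buys nothing measurable at this scale;
  the desk profile only needs to be a CNN that can learn the phantom's
  grade cues through the same adapter-plus-head surface.
* **Average pooling, not max pooling.** The discriminative feature is a
  *dark* band (the joint space) inside bright bone; max pooling erases thin
  dark structures, average pooling preserves their integrated contrast.
* **Anisotropic pooling.** Both grade cues live in the vertical intensity
  profile — the gap is a horizontal band a few pixels tall and osteophytes
  are small marginal bumps — so the early stages pool rows gently (2×) and
  columns aggressively (4×), keeping vertical resolution where the signal
  is while shrinking compute.

Training (`fit_knee_classifier()`) uses Adam with a reduce-on-plateau
schedule (factor 0.5) and early stopping, both monitored on validation
loss, restoring the best-validation weights at the end; batch size 16 and
learning rate 10⁻⁴ are the configuration defaults for fine-tuning-style
runs, while from-scratch desk runs use a larger rate (the experiment below
uses 2·10⁻³ with batch 8). Divergence (non-finite loss) aborts with the
epoch index. All stochastic stages draw their seeds from one global seed
via a splitmix-style derivation (`derive_seed()`), so stages can be rerun
independently.

## Metrics

`evaluate_predictions()` reports categorical cross-entropy (natural log,
probabilities clipped to [10⁻⁷, 1]), categorical accuracy (argmax match,
ties to the lowest class), one-vs-rest ROC AUC, and precision and recall
from one-vs-rest confusion counts. Multiclass averaging is **macro** over
classes present in the truth (the conservative convention), with a micro
AUC reported alongside; classes never predicted score precision 0 with a
warning rather than failing. AUC uses the rank (Mann–Whitney) statistic
with half-credit for ties, which equals trapezoidal integration of the
empirical ROC, and is tested against exhaustive pair counting and against
pROC. Precision (positive predictive value) is sometimes informally called
specificity; the two differ, so per-class true specificity TN/(TN+FP) is
exposed separately as `class_specificity()`.

## Classical baselines

`fit_baselines()` flattens each 224 × 224 slice to a 50,176-vector,
standardizes features with training-set statistics, and fits a decision
tree split on information gain (entropy), an RBF SVM with regularization
strength 0.5 and one-vs-one decisions, and a 500-tree random forest.
Baselines see the *original* training slices by default (augmentation is a
deep-model device; `use_augmented = TRUE` overrides). One divergence:
R's `randomForest` implements only the Gini criterion, so the forest is
Gini-split where an entropy criterion was specified; the tree uses entropy
as configured.

## The desk-scale experiment

`grade_recovery_experiment()` is the package's system-level check, sized
for a single CPU (the sizes are package choices, configurable): a training
cohort of 100 patients with a uniform grade mix (80/20 patient split, 2
augmented copies per slice, ≈430 training slices), the compact profile
trained up to 40 epochs (batch 8, learning rate 1.5·10⁻³); then two
*independently generated* evaluation
cohorts — 36 patients covering grades 2–4 only (72 knees) for macro
recall, and 110 bilateral films each carrying one grade-0 and one grade-1
knee (220 knees) for the confusability analysis. The expectation it tests:
severity grades 2–4, separable by construction, are recovered with macro
recall ≥ 0.8, while 0-vs-1 discrimination AUC stays within [0.4, 0.6] —
chance, since no pixel signal exists. With 110 knees per class the null
AUC's standard deviation is ≈0.039, so the chance band is ≈2.6 standard
deviations wide.

## Numerical choices and degenerate inputs

* Otsu rejects constant images ("degenerate histogram"); standardization
  rejects empty or one-pixel-wide inputs; `detect_knee_columns()` raises a
  typed condition carrying the run list when fewer than two runs qualify.
* Argmax ties break to the lowest class index everywhere.
* The Gaussian blur used by sharpening truncates its kernel at ±3σ and
  reflects at edges, so constants are preserved exactly and 5 × 5 toys
  work.
* Dropout is inverted (scaled at train time), so evaluation is the
  identity.
* Probability-row sums are validated (10⁻⁶ for metrics, 10⁻⁵ for the
  loss); AUC skips classes absent from the truth with a warning and errors
  on single-class truth.
* Zero learning rate is a supported edge (parameters provably untouched),
  used to test the optimizer plumbing.

## Limitations

Phantom geometry is deliberately minimal; none of the reported phantom
metrics are forecasts of clinical performance. The large ImageNet backbones
are exact *accounting* objects — building and training DenseNet-121 itself
is out of the desk profile's scope. Confidence intervals and k-fold
cross-validation are not part of the protocol reproduced here.
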