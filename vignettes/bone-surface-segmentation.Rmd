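---
title: "Bone-surface segmentation in B-mode ultrasound: model, losses, metrics and phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone-surface segmentation in B-mode ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In ultrasound-guided surgical navigation, the patient is registered to a
preoperative 3-D plan by matching bone-surface points detected in tracked
2-D B-mode frames. The bone surface appears as a thin, bright, curvilinear
echo with an acoustic shadow beneath it; fascia and muscle-layer boundaries
produce similar bright lines above the bone and are the dominant source of
false positives. In pediatric patients the cortical lining is less distinct
(bone marrow matures throughout childhood), so a model tailored to
pediatric imaging is needed. `boneseg` implements the full pipeline:
a lightweight tokenized-MLP encoder–decoder that segments the bone surface
as a thin curve, the compound loss that trains it, topology-aware
evaluation metrics, a cross-validated fold ensemble, and a synthetic
phantom generator that makes every stage testable without clinical data.

## The network

`unext()` builds a UNeXt-style hybrid:

* **Convolutional encoder** — three stages (1 → 16 → 32 → 128 channels),
  each 3×3 convolution + batch norm + ReLU + 2×2 max-pooling.
* **Tokenized-MLP bottleneck** — two overlapping patch embeddings
  (3×3 convolutions, stride 2) project to token widths 160 and 256, each
  followed by a shifted-MLP block: layer norm, a spatial shift of five
  channel groups by −2…+2 pixels along one axis, fc1 (d → d), a 3×3
  depthwise convolution with GELU, a shift along the other axis, and
  fc2 (d → d), with a residual connection. The shifts mix tokens spatially
  without attention, which keeps the parameter count low.
* **Decoder** — bilinear 2× upsampling with convolutions
  256 → 160 → 128 → 32 → 16 → 16; encoder features are fused by
  element-wise **addition** at matching resolutions (the channel plan of
  the decoder convolutions pins this down — concatenation would double the
  input widths). A final 1×1 convolution produces one logit map at input
  resolution. The network is fully convolutional; any input size divisible
  by 32 works.

`parameter_budget()` enumerates the 18 named layers. Their counts follow
the usual arithmetic (`k·k·c_in·c_out + c_out` for convolutions, `2c` for
batch norms, `d_in·d_out + d_out` for fc layers) and total 1,375,729; the
frequently quoted headline of "1.38 million parameters" corresponds to
this enumeration without the final 1×1 convolution's 17 parameters
(1,375,712). Normalisation layers inside the token blocks and the
depthwise convolutions are part of the network but outside the enumerated
budget: their sizes cannot be pinned down from the budget table alone, so
they follow the original UNeXt design. We include exactly one token block
per embedding width (160 and 256) and none in the decoder, because the
budget enumerates fc pairs only at those two widths.

Since no R deep-learning framework is available, the network, reverse-mode
differentiation (a small tape in `R/autograd.R` over C++ kernels), AdamW
and the LR schedule are implemented natively; correctness is enforced by a
finite-difference gradient test over every parameter tensor and by a
direct-convolution oracle test.

## The compound loss

Thin-curve targets are extremely imbalanced (the bone surface is ≪1% of
pixels), and plain overlap losses are nearly blind to topology. Training
therefore proceeds in two phases controlled by `loss_schedule()`:

1. **Warm-up (epochs 1–10)** — weighted binary cross-entropy only, with
   the positive-class term multiplied by 20. The weight applies
   multiplicatively to the positive term of the standard BCE; the loss is
   computed in a numerically stable form directly from logits and reduced
   by the mean over pixels, then over the batch.
2. **Dynamic blend (after epoch 10)** — the soft centerline-Dice loss is
   ramped in linearly so that the final epoch optimises a 50:50 blend.
   The ramp shape is not dictated by the two stated endpoints
   ("WBCE-only for ten epochs", "50:50 at the last epoch"); linear is the
   minimal assumption and a cosine ramp is available via
   `loss_schedule(ramp = "cosine")`. Blend weights always sum to one and
   the centerline weight is non-decreasing.

The soft centerline-Dice loss replaces hard skeletons with the iterative
soft skeleton (min-pool soft-erosion and max-pool soft-opening, residues
accumulated over iterations). Topology precision and sensitivity are
formed per frame with a smoothing constant `epsilon = 1e-6` and averaged
over the batch; the "50:50" endpoint is interpreted as equal raw weights
of the two differently-scaled losses. The default of 10 soft-skeleton
iterations thins any response up to ~20 px wide, ample for 192×192 (and
96×96) inputs; fewer iterations under-thin thick responses and bias the
loss optimistic.

## Metrics

All evaluation is done on **hard** morphological skeletons
(Zhang–Suen-type thinning, `skeletonize()`):

* `cl_dice()` — topology precision `|S_P ∩ V_L| / |S_P|` (prediction
  skeleton inside label mask; sensitive to false positives), topology
  sensitivity `|S_L ∩ V_P| / |S_L|`, and their harmonic mean.
* `mean_surface_distance()` — the **directed** label → prediction
  distance: for each of the N label-skeleton points, the Euclidean
  distance (per-axis mm spacing applied) to the nearest predicted-skeleton
  point; the mean of the N minima. Symmetric Hausdorff-type distances are
  deliberately not used: for open curves they are dominated by endpoint
  mismatch. The signed probe-axis offset averages
  `(label_row − pred_row) · row_spacing` over the same nearest pairs, so a
  prediction shallower than the label (toward the transducer at row 0) is
  positive.
* Empty-mask conventions (the definitions are silent): both masks empty
  scores clDice 1 (a correctly rejected empty frame); exactly one empty
  scores 0 and counts as a detection failure; the distance is undefined
  and excluded (and counted) whenever either skeleton is empty. This keeps
  aggregates finite while crediting the empty-label frames that exist
  specifically to suppress false detections.
* Predictions are binarised at probability 0.5 before skeletonization;
  aggregate tables report mean ± sample SD (n − 1).

Both metrics are verified against brute-force oracles (coordinate-set
counting; exhaustive pairwise distances) to 1e-9 on random masks.

## Training protocol

`train_fold()` runs AdamW (lr 1e-3, decoupled weight decay 5e-4). The
plateau rule halves the LR after 3 consecutive epochs without
validation-loss improvement, while the checkpoint kept is the epoch with
the best validation **clDice** — the two deliberately track different
quantities, by design. Validation metrics are always computed on
un-augmented frames. `crossval_unext()` assigns whole groups (patients) to
folds, trains one model per fold and returns the "weighted model": the
ensemble averaging per-fold sigmoid probabilities. "Weighted" is read as
ensemble-averaged with uniform weights; validation-clDice-proportional
weighting is available via `train_config(combine = "val_cldice")`.
Augmentation follows the reference recipe (blur σ 5, rotation ±10°, shear
±0.2, contrast 0.25–1.75) applied to an "arbitrary quarter" of the
training set, implemented as a per-sample, per-epoch Bernoulli(0.25) draw
rather than a fixed slice (order-independence after shuffling); each
enabled operation fires independently with probability 0.5, since no
composition rule is prescribed. Augmented frames replace the originals
(no dataset growth). Total epochs (60) and batch size (8) are declared
defaults — neither is pinned down by the reference protocol.

## The phantom: what it emulates, and what a green test means

`render_sample()` states a simple appearance model: a quadratic bone arc
(convex toward the probe, slope < 1 px/column so the 1-px label stays
8-connected), Gaussian echo cross-profile (σ 1.8 px, peak 0.9), a smooth
multiplicative shadow (factor 0.25) beneath the arc, layered soft tissue
with lightly smoothed multiplicative Rayleigh speckle, fascia-like
distractor lines that are always shallower and dimmer than the bone, and
global gain variation. Defaults mirror the clinical regime where stated:
192×192 frames, 0.2 mm/px (~38 mm field of view inside the 2–6 cm
imaging-depth range), an empty-label fraction of 363/4672, six anatomy
tags and two age groups as cosmetic strata. The row-0-at-transducer
convention is what gives the signed offset its meaning.

The phantom is deliberately *not* acoustically realistic: no fan geometry,
no depth-dependent attenuation or focus, no refraction, and anatomy tags
do not model pelvis vs rib shape. A green end-to-end test therefore
establishes that the implementation — architecture, loss schedule,
optimisation, ensembling, metrics — can recover a known bright-ridge
structure under speckle, shadow and distractors; it does not establish
clinical performance. Conversely the phantom reproduces the clinically observed
failure sources (fascia lines, empty frames), so false-positive behaviour
is exercised.

Numerical/degenerate-input choices: intensities are clipped to [0, 1];
speckle factors are clipped to [0.45, 1.5] so the echo ridge remains the
column maximum (the labels mark the ridge by construction); configurations
whose bone arc cannot fit inside the frame are rejected; warps that empty
a mask are flagged, not errors.

## Scaled-down verification

`phantom_benchmark()` (also driven by `scripts/acceptance.R`) runs the
whole method at desk scale: 240 frames at 96×96 (0.4 mm/px, 8% empty),
200 train-val / 40 test split disjoint by synthetic patient, a 2-fold
ensemble (reduced from 5) trained 20 epochs per fold on one CPU in a few
minutes. The held-out targets are the stated minimal clinical
requirements — mean clDice at least 0.75 and mean surface distance below
2 mm — which the phantom run meets with a wide margin (the test suite
asserts the fixed-seed run; a 3-seed reduced-scale robustness check runs
in the training tests). The scale reduction (image size, fold count,
epochs, dataset size) is purely for CPU budget; all method constants are
unchanged.

## Known limitations

* The clinical data is private; nothing here validates performance on real
  pediatric ultrasound, and per-age stratified clinical results can
  only be mirrored structurally (the report layout), not numerically.
* Global probe-direction offsets reported on clinical data are a property
  of that data; only the sign convention is implemented here.
* Double precision throughout; training is single-threaded apart from
  BLAS. At clinical scale (4672 frames, 5 folds, 192×192) a GPU framework
  would be the right tool — the native implementation targets desk-scale
  verification.
* Whether "predicted surface points" in the distance should be the
  prediction mask or its skeleton is ambiguous; skeletons are used,
  matching the distance-array definition on S_P.
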