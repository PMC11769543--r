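---
title: "Dual-stage kidney and kidney-tumor segmentation: models, metrics, and phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-stage kidney and kidney-tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Renal cell carcinoma is routinely assessed on contrast-enhanced CT (CECT),
where the enhancing kidney parenchyma is bright against soft tissue and
tumors appear as focal lesions of deviating attenuation. Small tumors
(unidirectional diameter ≤ 4 cm) are the clinically critical and technically
hard case: a whole-volume ("single-stage") segmentation network searches
hundreds of millions of voxels for a lesion of a few thousand, and bright
distractors far from the kidneys — most prominently the spine — generate
false positives.

`nephroseg` implements a coarse-to-fine ("dual-stage") framework:

1. **Stage one** segments the *kidney region* (kidney plus any tumor) and
   reduces each kidney to an axis-aligned volume of interest (VOI), expanded
   by 25% per axis so the second stage sees enough surrounding context.
2. **Stage two**, a residual 3D UNet with attention-gated skip connections,
   segments tumors only inside those VOIs. Outside the VOIs, tumor
   predictions are structurally impossible.

Everything needed to exercise the pipeline — preprocessing, augmentation,
both networks, training, inference, a size-stratified evaluation protocol,
and a synthetic CECT phantom generator — is in this package, with no
external data dependency.

## Preprocessing

The recipe follows the common large-cohort practice for CECT:

- **Percentile clipping.** The 0.5th and 99.5th percentiles of the *pooled*
  training voxels (linear interpolation between order statistics) define a
  clipping window. Pooled, not per-scan: the window and the moments below
  are dataset-level statistics, frozen at training time and reused verbatim
  at inference (`compute_intensity_stats()`, serialized into configs and
  checkpoints). A per-image mode exists behind a flag for ablation.
- **Isotropic resampling** to 1.0 mm via trilinear interpolation for images
  and nearest neighbour for label masks; output extents are
  `round(extent × spacing / target)` with halves rounded away from zero, so
  sizes are deterministic under any spacing ratio.
- **z-scoring** `(clip(v) − mean)/sd` with the pooled post-clip moments.
  Normalizing constant data is refused explicitly rather than returning
  NaNs.

## Training-time augmentation

`random_augment()` applies one sampled configuration of random rotations
(±30° per axis), scaling (0.85–1.25), mirroring (any axis), in-plane axis
transposition, and gamma correction (0.7–1.5) — geometric parts identically
to image and mask (linear vs nearest interpolation), gamma to the image
only. Magnitudes are defaults in the config, not claims: they follow common
3D segmentation practice. Rotations resample on the fixed grid, padding
with the image minimum, so patch geometry is stable.

## The networks

**Stage two — Kidney Tumor 3D UNet.** Six encoder stages at widths
32/64/128/256/320/320 with 1/3/4/6/6/6 residual blocks per stage; stage six
is the bottleneck, so a 192×128×128 patch reaches 6×4×4 at depth. Each
residual block is conv–instance-norm–LeakyReLU ×2 plus an identity (or
strided pointwise) skip; downsampling is a stride-2 convolution inside the
first block of each stage. The decoder mirrors the encoder with
kernel-2/stride-2 deconvolutions and one convolution per stage; each skip
connection passes through an additive attention gate (project skip and
gating features to a common width, add, nonlinearity, pointwise projection
to one channel, sigmoid, multiply into the skip). The head is a pointwise
convolution and sigmoid over a single tumor channel. LeakyReLU slope is
0.01; deep supervision is deliberately absent. `tumor_net_shape_pass()`
checks any patch symbolically, and `build_tumor_net()` instantiates the
graph; parameter count and topology are pure functions of the config.

**Stage one — organ network.** The default backend is a shifted-window
transformer encoder: patch embedding at half resolution, four steps of two
attention blocks (unshifted, then cyclically shifted windows), width
doubling between steps, and a CNN decoder of residual blocks with instance
normalization, deconvolution upsampling and a pointwise+sigmoid head. The
attention window is a config knob (default 4 per axis — chosen so windows
tile the feature grids exactly at every depth). Stage one is a pluggable
interface: a small pure-CNN residual UNet backend offers the same contract
and is the backend the CPU presets train. The stage-one *target* is the
kidney region (kidney ∪ tumor, i.e. label > 0), the usual convention for
organ localization; this makes VOI coverage of tumors a structural
property rather than a statistical one.

## Training

Both stages minimize DiceCE, `(1 − soft Dice) + BCE`, averaged over the
patch. The soft-Dice smoothing constant is 1 (not a tiny epsilon): with an
empty target patch, a vanishing constant makes the Dice term's gradient on
false positives effectively zero, leaving only the (weak, N-averaged) BCE
to suppress them; smoothing at 1 keeps a usable gradient in exactly the
patches that teach the network to stay silent.

Patches are sampled with foreground oversampling (default 0.5): with that
probability the patch is guaranteed to contain a uniformly chosen
foreground voxel, placed at a *uniformly random offset inside the patch*.
The offset matters: always centering foreground teaches the network a
position prior instead of an appearance model.

Layout consistency between training and inference turned out to be the
single most important correctness property of the whole training design,
worth stating as a rule: **the network must never see a voxel layout at
inference that it could not have seen in training.** Three mechanisms
enforce it here. (1) Stage-two VOI crops are extended to at least the
training patch extent *with real volume context* (`extend_box_to()`), in
training and inference alike, so patch-sized blocks always contain genuine
surroundings rather than artificial padding. (2) Where a grid is still
smaller than the patch (degenerate cases), training patches and inference
windows pad symmetrically with the same fill — a constant pad frame is a
spatial landmark the network will exploit if its position differs between
the two paths. (3) The sliding-window inference window *is* the training
patch size, never shrunk to fit the input. Violating any one of these cost
20–40 points of held-out Dice in controlled comparisons during
development, with training metrics unaffected — exactly the failure mode
that does not show up until a held-out evaluation.

Optimizers follow the two-stage convention: stage two uses nesterov SGD
(momentum 0.99) with polynomial learning-rate decay at base rate 0.001;
stage one uses AdamW at 3.5e-4. Epoch counts and schedules are
configuration. Runs are bit-reproducible for a fixed seed on a single CPU
thread.

The numerical engine is a small reverse-mode tape over C×N feature-map
matrices with Rcpp kernels: 3D convolutions lower to tiled im2col + BLAS
GEMM with hand-derived adjoints, and windowed multi-head attention is a
fused operation with an explicit backward pass. Every operator's gradient
is validated against central finite differences in the test suite.

## Desk-scale presets

The paper-scale configurations (six stages, 192×128×128 patches, batch 5)
are shipped as defaults of the config objects, but training them is a
GPU-cluster exercise. The desk presets (`desk_net_configs()`,
`desk_train_config()`, `run_desk_experiment()`) are sized for one CPU:
64³ phantoms at 1 mm, a 3-stage tumor net (8/16/32, attention gates on) on
24³ VOI patches for 25 epochs at SGD lr 0.01, and the CNN stage-one backend
(8/16/32) on 32³ patches for 10 epochs at AdamW lr 3e-3. The learning
rates are higher than the paper-scale defaults because the desk networks
are two orders of magnitude smaller and see a few hundred optimizer steps
rather than hundreds of thousands; the paper-scale defaults remain the
config defaults. Problem sizes (40 training / 10 held-out phantoms) were
chosen as the smallest cohort on which both stages train to useful accuracy.

## Evaluation protocol

Voxel-level metrics per instance and per case:
Dice `2TP/(2TP+FP+FN)`, precision `TP/(TP+FP)`, volumetric distance
`|FN−FP|/(2TP+FP+FN)`, over-segmentation ratio `FP/(TP+FN)`, and
under-segmentation ratio `FN/(TP+FN)`. Degenerate cases are defined, not
accidental: empty ground truth with an empty prediction scores Dice 1 and
VD/OSR/USR 0 (perfect negative); empty ground truth with false positives
leaves OSR/USR undefined (`NA`).

Detection is object-wise: tumors are 26-connected components, matched
one-to-one greedily by descending pairwise 3D IoU (deterministic
tie-breaks), with IoU ≥ 0.25 declaring a detection. Sensitivity is reported
per TNM size bin — small ≤ 4 cm, medium > 4–≤ 7 cm, large > 7 cm, with
small subdivided at 2 and 3 cm — and false positives are counted per
patient (FPC), binned by the predicted component's own diameter (an FP has
no ground-truth size). The unidirectional diameter is RECIST-style: the
largest pairwise voxel-centre distance within any single axial slice plus
one in-plane voxel, in cm; a true 3D Feret alternative is flag-selectable.
Per-category Dice is computed over detected tumors by default
("detected-only"), with an option to count undetected tumors as zeros —
both modes exist because reported tables rarely say which they use.

Paired per-case Dice distributions are compared with the two-sided Wilcoxon
signed-rank test (exact at small n without ties); Dice distributions are
bounded and skewed, so a rank test is the defensible default. Identical
inputs return p = 1.

## The phantom generator

`generate_phantom()` paints an abdominal scene analytically at voxel
centres: an air background (−1000 HU), a soft-tissue body ellipsoid
(40 HU), two kidney ellipsoids (120 HU, contrast-enhanced), a bright spine
cylinder (700 HU) as a deliberate false-positive decoy, and tumors as
ellipsoids at the kidney intensity plus an offset, intrarenal or exophytic.
Gaussian noise is added to the image only; the label mask is exact.
Tumor centres snap to voxel centres so a requested unidirectional diameter
is realized within one voxel. A tumor touching no kidney violates the
generator's contract and is refused.

`generate_cohort()` draws size categories by largest-remainder rounding of
the requested mix (default 54/24/22% small/medium/large, the typical
distribution of public kidney-tumor cohorts). Difficulty levels: *easy* is
high contrast (−50 HU vs kidney) with noise sd 10 HU; *hard* is low
contrast (|offset| ≤ 20 HU) with noise sd 25 HU. The desk preset (64³,
1 mm) holds 0.8–1.8 cm tumors; the full preset (96³, 2 mm) spans 1–10 cm.

What the phantoms do *not* emulate: CT physics (beam hardening,
reconstruction kernels), anatomical variability, cysts and benign masses,
multi-phase enhancement dynamics. Passing the phantom suite demonstrates
that the pipeline's mechanics — preprocessing, localization, VOI hand-off,
patch training, blended inference, the metric protocol — are correct and
that the networks can learn intensity-based discrimination; it says nothing
about clinical performance on patient scans.

## Numerical choices and edge cases

- VOI expansion is +25% of each axis extent (12.5% per side), then clipped
  to the grid; a volume reading of "25%" would give only ~7.7% per axis and
  starve stage two of context.
- At most two stage-one components (the two kidneys) become VOIs, smallest
  first discarded below a voxel-count floor; an empty stage-one mask yields
  an empty tumor mask and a "no kidney found" case.
- Overlapping VOI predictions merge by voxel-wise maximum probability
  before thresholding (0.5), so box seams cannot double-count.
- Sliding-window inference uses 50% overlap with Gaussian-weighted
  blending; an identity network reproduces its input exactly under this
  scheme (tested).
- Connected components use 26-connectivity everywhere (stage one, metrics,
  phantoms) for consistency.
- Mirror equivariance of the networks is a *trained-model* property here
  (checked as a Dice-stability assertion): stride-2 downsampling on
  even-extent grids breaks exact equivariance at the operator level, so no
  exact symmetry is asserted for untrained weights.

## Known limitations

- Arithmetic is double precision on CPU; paper-scale training is out of
  reach by design, and the desk presets are the supported training path.
- The shifted-window attention uses cyclic shifts without the attention
  mask that full implementations apply at volume borders; at phantom scale
  the effect is negligible, and stage one's CNN backend is the default for
  CPU training.
- Transfer-learning initialization is not supported; training starts from
  random weights.
- The phantom generator's realism limits are listed above; conclusions
  about patient data require patient data.
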