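---
title: "Dual-stage renal compartment segmentation in 4D DCE-MRI"
author: "renalseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-stage renal compartment segmentation in 4D DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dynamic contrast-enhanced (DCE) MRI of the kidneys acquires a 3D volume every
few seconds while a gadolinium tracer transits the organ. From a segmented
kidney — and, more finely, from its cortex and medulla — one can derive
clinically decisive markers: per-kidney time-intensity curves, filtration
estimates, and evidence of urinary-tract obstruction. Manual delineation at
this 4D scale is impractical, and paediatric data add severe difficulties:
kidneys from a few centimetres to adult size, congenital abnormalities
(hydronephrosis, multicystic dysplasia, missing kidneys), streaking from fast
radial undersampling, and motion blur.

`renalseg` implements a two-stage, fully modular answer:

1. **Learning-based whole-kidney segmentation.** A 3D residual U-Net
   localises the right and left kidneys as a coarse three-class segmentation
   from which per-kidney bounding boxes are derived; a 3D fully convolutional
   DenseNet then produces a voxel-wise kidney/background segmentation of each
   cropped region. Both networks see the scan through a compact
   spatio-temporal encoding (below).
2. **Rule-based cortex/medulla separation.** Within the whole-kidney mask, a
   per-slice contrast-maximisation cascade (intensity shifting, gamma
   correction, sigmoidal enhancement, exact Otsu thresholding) labels medulla
   and cortex candidates at *every* time frame, and a temporal fusion selects
   the optimum compartment labels across frames.

Because clinical DCE-MRI with expert compartment labels is not
redistributable, the package ships a first-class synthetic phantom generator
with exact ground truth; every claim the test suite makes is measured on
those phantoms.

## Spatio-temporal encoding of the scan

Both networks consume a fixed `(5, 64, 64, 64)` input built by
`preprocess_series()`:

1. **Temporal standardisation** (`resample_temporal()`): per-voxel linear
   interpolation onto 50 uniform samples covering the first 5 minutes,
   clamped at the acquired range. This makes the time axis comparable across
   protocols (the generator's default protocol is itself non-uniform: 3.3 s
   sampling for the 2-minute arterial phase, 13 s afterwards).
2. **Per-scan PCA** (`pca_reduce()`): each voxel's time course is mean-centred
   and projected on the leading 5 principal directions of the voxel-by-time
   matrix. The channels are ordered by explained variance; on phantoms the
   five channels explain essentially all temporal variance. PCA is fitted per
   scan, not per cohort — the encoding must work for a single unseen scan.
   Component signs are fixed by making each direction's largest-magnitude
   loading positive, so results do not depend on the eigensolver.
3. **Trilinear downsampling to 64³ and per-channel rescaling to [0, 255]**
   (network inputs are internally scaled by 1/255).

Linear interpolation in time and trilinear interpolation in space were chosen
as standard, monotone and cheap; nearest-neighbour resampling is used
whenever label volumes are moved between grids, which preserves binarity.

Training-time augmentation is available as `augment_sample()` /
`apply_augmentation()`: a seeded per-axis integer translation of 1–4 voxels
and a small (±4%) isotropic zoom, applied identically to image channels
(trilinear) and labels (nearest neighbour). The translation range follows
the reference training protocol; the zoom bound is the package's reading of
"scaled", kept small enough not to break the left/right class geometry.
Augmentation is applied when building training datasets, not inside the
optimisation loop, which keeps epoch losses strictly comparable and the
loop deterministic.

## The networks

**3D Rb-UNet (localiser).** Four encoder blocks (two 3×3×3 convolutions +
ReLU with an additive shortcut from the block input — a 1×1×1 projection
where channel counts differ — then 2×2×2 max-pool and dropout), a two-conv
bottleneck, and a decoder ending in batch normalisation and a 1×1×1
convolution to three classes (background / right / left kidney). The decoder
has five blocks: four perform 2×2×2 transpose-convolution upsampling with
same-scale skip concatenation, two convolutions and a residual add; the fifth
operates at full resolution without upsampling (four pooling stages admit
only four upsampling stages, so the fifth decoder block is the
full-resolution refinement before the head). Filter counts start at
`base_filters` (default 32) and double per scale.

**3D FC-DenseNet (segmenter).** A Tiramisu-style network: initial 3×3×3
convolution (48 filters), six dense blocks of 4, 5, 7, 10, 12, 15 layers on
the down path — every layer is BN → ReLU → 3×3×3 convolution producing
`growth_rate = 12` channels → dropout, concatenated to its input — with
transition-down blocks (BN, ReLU, 1×1×1 convolution compressing channels by
`reduction = 0.8`, dropout, 2×2×2 max-pool of stride 2) after the first five.
The up path has five transpose-convolution transition-ups, each followed by a
dense block of 12, 10, 7, 5, 4 layers with skip concatenation from the
same-scale down path; only the new feature maps of a dense block feed the
next transition-up (the standard Tiramisu economy), and the final 1×1×1
convolution + softmax sees the full concatenation of the last block. A
transition-down pool of stride 1 would not reduce resolution and could not
meet a five-level up path, so stride 2 is used.

**Normalisation.** Channel statistics are computed per input volume over its
spatial extent — exactly batch normalisation at batch size one. Mini-batches
(default 4) are trained by gradient accumulation. This is the practical
choice for volumetric inputs of this size and keeps training strictly
deterministic under a fixed seed.

**Loss.** Both networks minimise a weighted binary cross-entropy summed over
voxels and output channels and averaged by the voxel count, with per-voxel
weights inversely proportional to the prior of the voxel's true class
(normalised so background weighs 1, computed from the training set). The
summation bound in the loss is read as "over all N voxels per channel" — the
only reading consistent with N being the number of voxels in a volume.
Probabilities are clamped at 1e-7 inside the logarithms.

**Optimisation.** Adam with initial learning rate 1e-4, halved every 50
epochs, weight decay 1e-8, dropout 0.2, mini-batch 4, up to 400 epochs.
These are the reference settings; the test suite and the acceptance script
scale them down (learning rate 1e-3, 5–10 epochs, dropout 0, growth rate 2,
8–32 filters, 32³ inputs) so that training completes in minutes on one CPU.
All kernels (im2col/BLAS 3D convolution, transpose convolution, max-pooling)
are single-threaded C++ and bit-deterministic; identical seeds give identical
loss histories.

**Testing-stage conventions.** The localiser's argmax classes are mapped back
to original-resolution coordinates by the inverse of the downsampling scale
and enclosed in minimum bounding boxes; an empty class produces the
missing-kidney convention — a single-voxel box flagged `present = FALSE` —
and the downstream stages skip that side. The segmenter's binary output is
resampled to the crop size (nearest neighbour) and pasted back at the box
offset. Training labels for right/left are split at the mid-x plane of the
volume (patient right on image left).

## The compartment cascade

Let `D` be the slice depth. Central slices — the 1-based indices `d` with
`r_f * D <= d <= r_l * D` (defaults 0.3, 0.7; the real-valued bounds are the
products themselves, so the index set is `ceiling(r_f D) .. floor(r_l D)`) —
receive *intensity shifting*: every strictly interior intensity
(`a_min < s < a_max`, extremes excluded) is reduced by the minimum non-zero
intensity `a_min`. Peripheral slices receive *gamma correction*
`s <- (s/255)^gamma * 255` (default `gamma = 1.5`; much larger values darken
bright regions far more aggressively and are admissible through the same
parameter). All slices then pass through the *sigmoidal enhancement*
`E(s) = 1/(1 + exp(delta (mu - s)))` on the `[0, 1]` scale (defaults
`delta = 2`, `mu = 1.5`); with `mu` above the intensity range the curve is a
strictly monotone contrast stretch, so the subsequent threshold classes are
intervals of the original intensities.

*Otsu's threshold* is then computed **exactly** — candidates are the sorted
unique values, the maximised criterion is the between-class variance, ties
break to the lowest maximiser; no histogram binning — over the pixels inside
the fully closed whole-kidney mask slice. Restricting the histogram to the
kidney is deliberate: the cascade's markers are defined on non-zero
intensities, and a background-dominated histogram would make the threshold
separate kidney from background instead of cortex from medulla, rendering
the labelling rule vacuous. Pixels above the threshold are cortex
candidates; within the mask, sub-threshold pixels become medulla (label 1)
and the rest cortex (label 2).

"Fully closed" is implemented as morphological closing (disc, radius 2 at
1.25 mm in-plane resolution) followed by hole filling. Hole filling matters:
the Process-3 refinement relabels as cortex any masked pixel that is medulla
in the fused volume but background in the fully closed binarised reference
slice. If closing left the ring interior open, that rule would erase *all*
interior medulla; with hole filling it does precisely its job — correcting
peripheral slices where a contrast-free (degenerate, all-cortex) slice was
provisionally labelled all-medulla.

The temporal fusion (`process3()`) takes the reference volume at frame
`t_x = round(x T)` with `x` in `[0.25, 0.50]` (default 0.375, the midpoint —
a frame after the cortical peak where corticomedullary contrast is still
strong). For every frame and central slice whose medulla fraction `rMA`
(percentage of medulla in the labelled area) lies strictly inside
`(alpha, beta) = (30, 60)`, reference cortex pixels that frame saw as
medulla are promoted to medulla; slices with undefined `rMA` are skipped.
Finally the rim of the whole-kidney mask — dilation minus erosion with a
radius-1 cross, a thin band at this resolution — is labelled cortex. The rim
necessarily extends one pixel beyond the mask; the containment guarantee is
therefore "labels within the 1-pixel dilation of the closed mask". Left and
right kidneys are processed independently and merged (their masks are
disjoint).

## The phantom generator

`generate_phantom()` emulates the statistical structure the pipeline
assumes, not MR physics:

* Geometry: up to two ellipsoidal kidneys either side of the sagittal
  midline (defaults: 32 × 224 × 224 voxels at 3 × 1.25 × 1.25 mm, semi-axes
  proportional to the volume). Each kidney is a cortical shell (default 3
  voxels) around 2–4 ellipsoidal medullary lobes; the cortex is defined as
  kidney-minus-medulla so that, as in real parenchyma where cortical columns
  separate the pyramids, the two labels partition the whole-kidney mask.
* Kinetics: per-compartment enhancement curves — baseline, linear rise to
  `baseline + amplitude` at the time-to-peak, exponential washout. Defaults
  (cortex: 60 + 120 peaking at 40 s, washout 0.003/s; medulla: 50 + 80
  peaking at 90 s, washout 0.002/s; on a [0, 255] intensity scale) give the
  canonical pattern of early cortical and delayed medullary enhancement.
  The time base defaults to the two-rate acquisition protocol (3.3 s / 13 s,
  switch at 2 minutes, 6-minute cap).
* Noise and artefacts: additive Gaussian (or Rician magnitude) noise of
  configurable sigma (default 2), optional radial streak patterns with
  random per-frame phase, optional per-frame Gaussian blur. Severity is a
  free parameter — clinical artefact levels are qualitative, so amplitudes
  are configuration, not calibration.
* Abnormal variants: `missing_kidney` (one side absent) and
  `dilated_pelvis` (an enlarged, poorly enhancing central collecting
  system).

Everything is a deterministic function of the seed.

**What the phantoms do not show.** They contain no surrounding organs, no
partial-volume mixtures at compartment boundaries, no motion between frames
and no spatially varying coil sensitivity. Passing the suite therefore
demonstrates the correctness and internal consistency of the implementation
— exact thresholds, exact geometry handling, learnability, recovery of known
kinetics — not clinical-grade accuracy; the clinical accuracy of this class
of pipeline can only be established on expert-labelled patient data.

## Numerical choices and degenerate inputs

* Otsu ties break to the lowest maximising threshold; constant slices are
  flagged and labelled all-medulla provisionally (Process 3 corrects them).
* Empty masks raise a typed `kidney_absent` condition; absent kidneys are
  single-voxel `present = FALSE` boxes end to end.
* Dice/precision/recall conventions: both volumes empty gives 1 (warned);
  an empty denominator against a non-empty counterpart gives 0. Cohort
  standard deviations are sample SDs.
* Zero-variance PCA input yields zero explained-variance ratios, no crash.
* Resampling uses pixel-centre alignment and is the identity when the grids
  match.
* Curve baselines use the first acquired frame; a zero baseline falls back
  to absolute differences.

## Desk-scale problem sizes

The suite and `scripts/acceptance.R` use phantoms of 24 × 64 × 64 (rule
stage, 12 frames) and 24 × 48 × 48 voxels (network training, 10 frames),
32³ network inputs, growth rate 2 / 8 base filters, and 5–10 epochs. These
sizes were chosen so that the complete pipeline — generation, training,
segmentation, evaluation — runs in a few minutes on a single CPU while still
exercising every architectural element at full depth (all 11 dense blocks,
all residual scales). The full-size 64³ forward passes of both reference
architectures are exercised once in the acceptance tests.

## Known limitations

* The learning stage is CPU-bound R/C++; it is meant for correctness and
  desk-scale experiments, not for training on clinical cohorts.
* The sigmoid cut-off `mu = 1.5` sits above the normalised intensity range,
  making the enhancement a monotone stretch rather than an S-shaped
  remapping around a mid-grey; this follows the validated parameter setting,
  and the cascade's correctness does not depend on it (any monotone map
  preserves Otsu classes).
* Tracer-concentration conversion and filtration-rate fitting are out of
  scope; the package stops at labels and time-intensity curves.
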