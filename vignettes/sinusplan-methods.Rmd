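---
title: "Landmark-guided sinus-augmentation planning: models, phantoms and design choices"
author: "sinusplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-guided sinus-augmentation planning: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical problem

Implant placement in the posterior maxilla is constrained by the residual
bone height (RBH) between the alveolar crest and the maxillary sinus
floor.  A modified ABC classification maps RBH and ridge-defect status to
five surgical approaches (A, B, B′, C, C′), from simple implant placement
(abundant bone, RBH > 10 mm) through transcrestal osteotome elevation
(6–9 mm) to lateral-wall sinus elevation (≤ 5 mm), with guided bone
regeneration (GBR) added when a horizontal or vertical ridge defect is
present.  `sinusplan` automates this decision from a CBCT volume in two
stages: landmark detection and distance-guided classification.

## Stage 1: cascaded heatmap regression

Five landmarks define the measurements: the alveolar crest (AC), the
sinus floor (SF), the medial and lateral points of the horizontal bone
width (MH, LH) and the adjacent cementoenamel junction (CEJ).  Each
landmark is represented as a 3D Gaussian heatmap

$$H = \exp\!\left(-\frac{D^2}{2\sigma^2}\right),$$

where $D$ is the Euclidean distance (voxels by default, mm optionally for
anisotropic grids) from each voxel to the landmark and $\sigma$ controls
the width.  The heatmap is a *soft segmentation* target: values lie in
[0, 1], decrease monotonically with distance, and peak at the landmark
voxel.  Networks regress these maps with voxel-wise binary cross-entropy,

$$CE(H, P) = -\tfrac{1}{n}\sum_i \left[H_i\log P_i + (1-H_i)\log(1-P_i)\right],$$

with predictions clipped to $[10^{-7}, 1-10^{-7}]$ for numerical safety.

The detection network is a 3D U-Net-style encoder–decoder: 3×3×3
convolution + batch-norm + ReLU blocks, stride-2 max-pooling, stride-2
transposed-convolution upsampling, and three encoder-to-decoder skip
connections at the default depth of four levels (widths 8, 16, 32, 64,
i.e. doubling from `baseChannels`).  Three optional sub-modules:

* **MSI (multi-scale inputs).**  The input volume is average-pooled 2×2×2
  per level and concatenated as an extra channel at each encoder level,
  mitigating information loss through pooling.
* **convLSTM.**  At the bottleneck a bidirectional convolutional LSTM
  runs over the axial-slice axis (3×3 in-plane gate convolutions, hidden
  width equal to the bottleneck width; the two directions are
  concatenated and projected back by a 1×1×1 convolution).  This captures
  inter-slice context beyond the convolutional receptive field.
* **DS (deep supervision).**  Each decoder level emits a side output
  (1×1×1 convolution + sigmoid, nearest-upsampled to full resolution) and
  the training loss is the sum of the three side-output cross-entropies,
  $FL = CE_1 + CE_2 + CE_3$.  The level-1 side output *is* the
  full-resolution head used at inference — a deliberate resolution of an
  ambiguity: if the head sat outside the deep-supervision loss it would
  receive no gradient.  Side outputs at coarser levels are train-time
  only.

Detection is coarse-to-fine.  The coarse network sees the whole volume
block-averaged by `coarseDownsample`; each decoded peak seeds a
volume-of-interest (VOI) patch at native resolution, which the fine
network re-predicts.  VOI patches are clamped inside the volume rather
than zero-padded, so the fine stage never trains on fabricated
intensities, and the patch offset maps patch coordinates back to parent
coordinates exactly.  Peak decoding uses the intensity-weighted centroid
of the voxels holding the top 5 % of heatmap mass around the global
argmax (ties seeded at the lowest linear index; a small relative
tolerance keeps numerically tied voxels in the set), which recovers
sub-voxel positions to well under half a voxel on synthesised Gaussians.
A constant (degenerate) coarse channel flags its landmark as undetected
rather than guessing; a degenerate fine channel falls back to the coarse
estimate.

One coarse model carries all five landmark channels; one fine model is
applied per-landmark VOI and supervised only on the target channel.  This
keeps two models in total while preserving per-landmark patches.

## Stage 2: distance-guided classification

The classifier input has two channels — the min-max-normalised CBCT
intensities and the voxel-wise *maximum* over the five predicted heatmaps
(a symmetric fusion that preserves the published two-channel input; a
six-channel per-landmark variant is available via `heatmapFusion =
"channels"`).  After the conv/pool stages and 3D global average pooling,
the three **distance priors** — |AC−SF|, |MH−LH|, |AC−CEJ| in mm,
computed from the *predicted* landmarks both at training and at inference
— are divided by 20 (so they are O(1); the divisor is configurable) and
concatenated to the pooled features before a dense softmax head over the
five classes.  Ties in the argmax are broken in the fixed class order A,
B, B′, C, C′.  Training uses categorical cross-entropy under the same
optimiser contract as the detector.

## The rule engine

`classifyRBH()` implements the classification table as a total function.
The published anchors ("greater than 10 mm", "6–9 mm", "5 mm or less")
leave (5, 6) and (9, 10] mm unassigned; the package completes them
monotonically as C: (0, 5], B: (5, 10], A: (10, ∞) — the only monotone
completion consistent with the anchors — and the boundaries are
configurable.  Ridge defects are given explicit numeric criteria (the
clinical definition is qualitative): a horizontal defect is a width
|MH−LH| below 6 mm, a vertical defect a step |AC−CEJ| above 3 mm, both
configurable through `defectThresholds()`.  RBH is the straight-line
|AC−SF| distance, consistent with the classifier's absolute-distance
priors; a vertical-component mode (`rbhMode = "vertical"`) mirrors
perpendicular clinical measurements.

## The synthetic phantom

Clinical CBCT data cannot ship with the package, so every pipeline stage
is exercised on a synthetic phantom of the posterior maxilla built from
minimal analytic shapes that make all five landmarks well defined:

* an alveolar ridge modelled as a bone slab whose crest plane carries AC
  at the midline and MH/LH at the slab corners (the crest surface rises
  steeply outside the ridge width, so the corners are genuine geometric
  features);
* a sinus floor modelled as a paraboloid air–bone interface whose apex
  sits exactly `rbh` mm above the crest (SF), perturbed by a smooth
  radial undulation that vanishes at the apex so the landmark never
  moves;
* an adjacent tooth modelled as a high-intensity cylinder whose crown
  bulges below the cementoenamel junction; the CEJ landmark is the
  mesial cervical point, placed directly inferior to AC so that |AC−CEJ|
  equals the vertical step exactly.

Landmarks are exact analytic world-mm points; consequently the stored
class label always equals `planFromLandmarks()` applied to the ground
truth, and inter-landmark distances are resolution invariant.  Each
sample randomises the ridge position, floor curvature, wall slope, tooth
radius, tissue levels (±5 %) and additive Gaussian intensity noise, with
interfaces softened over ~0.7 voxel so sub-voxel localisation is
meaningful.  Scanner variation can be emulated through the voxel spacing
(0.15 / 0.25 / 0.3 mm are typical clinical values; the desk-scale study
uses 0.4 mm).

`generateDataset()` controls the class mix exactly (largest-remainder
rounding), sampling RBH uniformly within each class's interval — C/C′ in
(1, 5], B/B′ in (5, 10], A in (10, 15], spanning the published anchors
and filling their gaps consistently with the rule engine — and drawing
horizontal, vertical or combined defects with a 0.5 mm margin from the
defect thresholds so labels are unambiguous under discretisation.

What the phantom does *not* emulate: metal and motion artifacts, sinus
pathology (mucosal thickening, septa), anatomical variation beyond the
parameterised geometry, scanner-specific noise spectra, and neighbouring
anatomy (tooth roots in the sinus, nasal cavity).  Passing tests
therefore demonstrate that the implementation is correct and that the
method recovers parameters under controlled conditions — not clinical
performance.

## Optimisation and the desk-scale study

Training uses RMSprop (ρ = 0.9, ε = 10⁻⁷) with a reduce-on-plateau
schedule: the learning rate is multiplied by 0.5 whenever the validation
loss fails to improve for 25 consecutive epochs, each completed plateau
reducing it exactly once.  The reference protocol is 300 epochs at
learning rate 10⁻⁴ with batch size 8; augmentation draws one rotation in
[−25°, 25°] about the axial axis, one isotropic rescale in [−10 %,
+20 %] (applied identically to volume and landmarks — note a rescale
changes true distances, so heatmap targets are re-encoded from the
transformed landmarks), and brightness/contrast jitter.  Saturation and
hue have no meaning on single-channel volumes and are deliberately
reduced to brightness/contrast (with an optional gamma jitter off by
default).  Side-output biases are initialised at the logit of the
expected positive heatmap mass, so the sigmoid heads emit the correct
base rate from the first step instead of spending optimiser budget
learning it.

The package's test and acceptance suites run a **desk-scale study**
chosen once and documented here:

* phantoms: 64³ voxels at 0.4 mm (25.6 mm field of view), 200 training
  (split 180/20 train/validation, mirroring a 9:1 clinical split) and 40
  held-out test samples, equal class mix;
* coarse stage: base width 4, four levels, on the 4×-downsampled 16³
  grid (the downsample factor keeps the whole-volume receptive field
  while making repeated CPU training practical);
* fine stage: base width 4, three levels, 12³ VOI patches at native
  resolution, one landmark per volume per epoch (cycling through the
  five);
* heatmap σ = 2 voxels at both stages — σ is a free hyper-parameter of
  the method; on 16³ grids the larger defaults used at clinical
  resolution would blanket the entire grid;
* 30 epochs at learning rate 10⁻³ — the study runs roughly a tenth of
  the reference protocol's optimisation steps, and the rate is scaled up
  tenfold to compensate; the package default remains 10⁻⁴;
* classifier: widths 8/16/32 on an 8³ input grid (the decisive signal is
  carried by the distance priors; the image/heatmap channels provide
  context), 50 epochs;
* the sub-module ablation (full MSI+convLSTM+DS versus convLSTM alone)
  compares coarse-stage detection under a further-reduced but *identical*
  protocol for both arms (96/12 phantoms, 15 epochs, three seeds), which
  preserves the direction of the comparison at a fraction of the cost.

Under these conditions the cascade typically reaches a held-out mean
radial error of 0.5–0.8 mm with SDR(≤2 mm) of 93–96 %, and the
distance-guided classifier recovers the rule-derived class for 87–93 %
of held-out phantoms.  Desk-scale training is short enough that an
occasional seed leaves one landmark channel under-converged (an SDR
ladder plateauing near 80 %); robustness claims are therefore always
made over several training seeds.  `scripts/acceptance.R` recomputes
all of these quantities from scratch at one seed.

## Numerical choices

* All distances everywhere are world-mm; voxel indices are 0-based and
  continuous, with `world = origin + index × spacing` (axis-aligned
  volumes; the paper's acquisitions are never oblique).
* Intensities are min–max rescaled to [0, 1] per volume before entering
  any network (the source scanners mix 16-bit ranges).
* The network engine is double precision throughout; convolutions are
  direct (no im2col buffer) with register-blocked C++ kernels, templated
  on the channel count and dispatched at run time to an AVX2+FMA build on
  CPUs that support it.  Every backward pass is hand-derived and verified
  against central differences in the test suite.
* Batch-norm uses batch statistics during training (momentum 0.1 running
  estimates at inference, ε = 10⁻⁵).
* SDR thresholds are inclusive (error ≤ threshold); boundary cases are
  measure-zero on continuous errors.
* Multi-class AUC is one-vs-rest with macro averaging; ties contribute
  half a concordance.  Fleiss kappa uses the large-sample standard error
  under the null, matching the convention of a single SE/Z/p per
  category.
* Majority votes must be strict; a tie (e.g. a 1/1/1 split) returns an
  adjudication flag, never a silent choice.

## Known limitations

* Phantom realism, as above; no claim of clinical performance transfers
  from phantom results.
* The convLSTM's placement and direction, the fine stage's weight
  sharing across landmarks, and the role of side outputs at inference are
  under-determined by the published description; the package's choices
  (bottleneck bidirectional LSTM, one shared fine model, train-time-only
  side outputs with the head as level-1 output) are exposed as
  configuration where sensible.
* Training is CPU-bound and single-threaded deterministic; the engine is
  sized for desk-scale studies, not clinical-resolution (256³) training.
* DICOM ingestion is out of scope; volumes enter as NIfTI.
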