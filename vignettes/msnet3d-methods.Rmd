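---
title: "MS-Net in R: model, training schedule, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MS-Net in R: model, training schedule, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msnet3d)
```

## The model and its assumptions

MS-Net assesses the malignancy of a lung nodule from CT while treating
inter-observer disagreement as signal rather than noise. Its inputs are a
*nodule cube* — an intensity crop around the nodule's consensus centre,
identical for every reader — and a *mask cube* — one specific reader's
binary segmentation cropped with the same geometry. The mask channel is
the observer-specific information: feeding the pair `(nodule, mask_r)`
for each reader r simulates that reader re-diagnosing the same nodule.

Stage one (FDID) extracts a shared feature with 3D-BcResNet50 and runs
ten parallel prediction heads: eight binarised semantic attributes, an
*individual* diagnosis (the current reader's opinion) and a *panel*
diagnosis (the reader panel's aggregate opinion). Stage two (DR) fuses
the ten 2-d predictions into a 20-d vector — semantic attributes in the
canonical order `r paste(semantic_features(), collapse = ", ")`, then
individual, then panel — and refines the two diagnoses. The class
convention everywhere is index 1 = benign, index 2 = malignant.

The backbone's bottleneck convolution (BConv) splits its input channels
into parallel grouped convolutions of kernel sizes 7/5/3 and
re-concatenates them, giving multi-scale receptive fields at bottleneck
cost. The default configuration follows the published stage table: a 7³
stride-2 stem (64 channels), stages of 3/4/6/3 residual blocks with
reduce widths 48/96/192/384 and 4× expansion, branch layouts
(7,8,G8)(5,8,G4)(3,16,G1)(5,8,G4)(7,8,G8) in stage 1 (scaled analogues in
stages 2–4), global average pooling, and a 1536→1024 fully connected
layer. An 80³ input traverses spatial sizes 40/20/10/5.

Three details of the stage table are under-determined and resolved here
as package design choices: the stem row lists stride (2,2,2), so the stem
output is taken as 40³ with no pooling layer and downsampling thereafter
by stride-2 first blocks of stages 2–4 (the only reading consistent with
the 40/20/10/5 ladder); the stem width, unstated, is 64 (conventional
residual-net stem); each BConv branch carries its own batch
normalisation and rectifier (per-branch order conv → BN → ReLU,
block exit expand-conv → BN, residual add, ReLU — standard bottleneck
ordering). The crop side is interpreted as 80 *voxels* after resampling,
not 80 mm: at spacing (0.68, 0.68, 1.75) mm an 80 mm cube would be
≈118×118×46 voxels and could not feed the 80³ network input.

## The collaborative loss

One-hot training on individual labels over-trusts the current reader;
collapsing to the panel label erases the individual opinion. The
collaborative loss softens the individual head's target with the panel
label:

$$q'(k) = (1-\varepsilon)\,\delta_{k,y_0} + \varepsilon\,\theta_{k,y_1},
\qquad
L_{cb}(q',p) = -\sum_{k=1}^{2} q'(k)\log p(k)
 = (1-\varepsilon)H(q_0,p) + \varepsilon H(q_1,p),$$

with $y_0$ the individual and $y_1$ the panel label and
$\varepsilon = 0.6$ by default — note that $\varepsilon$ weights the
*panel* label, so agreement gives `[1, 0]` and (benign, malignant)
disagreement gives `[0.4, 0.6]`. Both distributions are realised as
one-hot vectors of the binary labels; the printed encodings are only
reproducible under that reading. The natural logarithm is used, with
probabilities floored at 1e-12. The loss is affine in $\varepsilon$ with
slope $H(q_1,p) - H(q_0,p)$, and $\varepsilon = 0$ recovers ordinary
per-annotation cross-entropy.

The panel head is supervised symmetrically, with the individual opinion
as the reference: $q' = (1-\varepsilon_p)\,\mathrm{onehot}(y_1) +
\varepsilon_p\,\mathrm{onehot}(y_0)$. Whether $\varepsilon_p$ should be
0.6 or 1−0.6 is not determined by the source material; the package
defaults to 0.6 for both (configurable per head in
`msnet_train_config()`). A consequence worth recording: with
$\varepsilon = 0.6 > 0.5$ the individual head's target actually carries
*more* panel weight (0.6) than the panel head's own-label weight (0.4),
so on panel-label ground truth the two refined heads are trained toward
mirror-image mixtures of the same two labels and their held-out
accuracies are expected to be close to identical — which is exactly what
the synthetic experiments show (a tie to three decimals at the default
settings). Semantic heads use plain cross-entropy: label softening is
defined only for the two diagnosis opinions. DR heads use the
collaborative loss in the joint stage, consistent with their outputs
being refined individual/panel opinions.

## Cohort and label rules

* Individual cohort: only nodules read by ≥ 3 radiologists on scans with
  slice thickness < 3 mm; each retained annotation is an independent
  case; ratings 1–3 → benign, 4–5 → malignant.
* Panel labels: mean rating < 3 → benign, > 3 → malignant, exactly 3 →
  excluded (sentinel `NA`). Excluded cases are dropped from panel-label
  experiments but kept in individual-label experiments, which is why the
  two cohorts differ in size.
* Semantic binarisation: calcification levels 1–5 vs 6; the other seven
  features levels 1–3 vs 4–5 (internal structure, a 1–4 scale, maps
  4 → 1 by the same reading).
* Nodule identity: annotations are grouped by explicit key when present,
  else by single-linkage centroid distance ≤ 5 voxels; a group whose
  centres spread beyond the threshold is flagged ambiguous and excluded,
  a deterministic stand-in for the source's unspecified "ambiguous IDs".
* Ratings are validated, never clamped — silent clamping hides data
  errors.

## Preprocessing and augmentation

Scans are resampled to (0.68, 0.68, 1.75) mm with nearest-neighbour
interpolation (masks stay binary), windowed to [−1200, 600] HU and
rescaled to [0, 1]. The crop is centred on the rounded component-wise
mean of the readers' centres (half-up rounding on each axis); regions
outside the volume are zero-padded (0 = normalised air). Internally all
voxel coordinates are 1-based (R convention); manifests on disk are
0-based.

Training-time augmentation draws, independently per sample with
probability 0.5 each: an integer translation with per-axis step from
0–5 voxels (direction drawn separately), a random axis permutation
followed by an in-plane rotation of 45°/135°/225° (intensities linear,
masks nearest-neighbour), and independent per-axis flips. Malignant
samples are replicated round-robin until the class counts match within
one; replicates draw fresh augmentations. Balancing is keyed to the
individual label by default (each annotation is a case in the individual
cohort) and configurable to the panel label.

## Two-stage training

Stage 1 (epochs 1–40, lr 0.01) trains FDID only: the DR branches are not
run, receive no gradient, and their parameters are provably untouched.
Stage 2 (epochs 41–80, lr 0.0001) trains FDID and DR jointly; the DR
loss gradient flows through the fused probabilities (not logits — the
predictions are fused post-softmax) back into the heads and backbone.
SGD uses batch size 8 and momentum 0.9 (momentum is unstated in the
source; 0.9 is the conventional default, configurable), Xavier
initialisation (Glorot-uniform with conv fans `k³·C/groups`), zero
biases, BN scale 1 / shift 0. A single global learning rate is used in
each stage. Model selection keeps the best validation accuracy on the
refined panel head (or refined individual head for individual-label
experiments).

## The desk-scale (micro) profile

The published settings assume GPU-scale training. For CPU-scale
validation the package ships `msnet_micro_profile()`: quarter-width
backbone on 32³ cubes with **one** residual block per stage, 256-d
shared feature, 32-wide heads and DR branches, and a 10-epoch schedule —
5 FDID-only epochs at lr 0.01, then joint training at lr 0.003, with a
within-stage decay of 0.85/epoch, momentum 0.5, batch 8, malignant
rebalancing, no augmentation. These choices are the profile's own: with
only ~100 gradient steps, momentum 0.9 oscillates, a 1e-4 joint rate
would leave DR effectively untrained, and 9 residual blocks optimise too
slowly — one block per stage reaches the same task accuracy in a tenth
of the steps. The full-run defaults of `msnet_train_config()` remain
exactly the published values.

## The synthetic phantom generator

`phantom_config()`/`build_phantom_set()` generate 3D nodule phantoms
carrying the statistical structure the network assumes:

* **Shape.** An ellipsoid (radii 0.14–0.26 of the cube side) on smoothed
  background noise in [0, 0.3]. Malignant shapes add 6–12 radial spikes
  (relative amplitude 0.3–0.5; a von-Mises-like angular profile with
  concentration 12, broad enough that spiculation is resolvable at the
  32³ micro side as well as at 80³), 1–3 surface lobes, and stronger
  margin blur (σ 1.0–2.0 vs 0.4–1.0 mm-scale voxels); benign shapes are
  smooth (amplitude ≤ 0.06, no lobes). An optional bright calcification
  core (intensity 0.95) is more frequent in benign nodules. Texture type
  (ground-glass / part-solid / solid) sets the nodule intensity
  (0.45/0.6/0.7).
* **Latent malignancy.** The documented monotone link
  `clip(1.5 + 5.5·amplitude + 0.5·lobes, 1, 5)` keeps smooth shapes in
  the benign band (< 3) and spiky, lobed ones above 3.5, reflecting the
  radiological prior that burr-shaped and lobulated nodules are more
  often malignant.
* **Readers.** Each of R readers (default 4) perturbs the true mask by a
  random ball dilation/erosion of radius ≤ `mask_jitter` (Dice ≥ 0.7
  enforced), rates malignancy as
  `clip(round_half_up(latent + N(0, σ)), 1, 5)` with σ =
  `rating_noise_sd` (default 0.7), and reports semantic scores as
  deterministic monotone maps of the shape parameters plus ±1 ordinal
  noise. σ = 0 gives exact, noise-free readers.
* **Cohort.** The malignant fraction (default 0.36, the panel cohort's
  class share) is realised exactly to rounding; nodules are assigned to
  train/validation/test 60/20/20, stratified by class, at the nodule
  level so annotations never straddle splits.

What the phantoms deliberately do **not** emulate: anatomical context
(vessels, pleura), realistic CT texture, scanner heterogeneity, and
rating noise that correlates with the reader's own mask. Passing the
synthetic checks therefore demonstrates that the architecture, losses,
schedule and plumbing work and that the network can learn 3D shape–label
relationships from multi-reader data — not clinical-grade performance on
real CT.

## Numerical choices

* All computation in double precision; softmax with max-subtraction;
  probabilities floored at 1e-12 before logs; BN ε = 1e-5, running-stat
  momentum 0.1 (unbiased variance in the running estimate).
* Nearest-neighbour resampling maps output voxel centres to nearest
  input voxel centres; grid size `round(n·spacing/target)` per axis.
* Half-up rounding for all centre/rating rounding (R's `round()` is
  half-even and platform-stable but surprises here).
* Dropout is inverted (scaling at train time); evaluation-mode forwards
  are pure functions of (weights, input).
* Deterministic grouped 3D convolution via per-group im2col + BLAS gemm;
  1×1×1 stride-1 convolutions short-circuit to a plain gemm.
* Seeds: phantom content is deterministic in (config, index); training
  consumes a single R RNG stream seeded from the run config, so a fixed
  seed reproduces shuffling, augmentation and dropout bit-for-bit on one
  device.

## Validation suite and problem sizes

The test suite validates the engine against independent oracles (naive
triple-loop convolution, central finite differences, brute-force label
enumeration over all 5⁴ rating vectors, analytic parameter counting
against a layer-walking enumeration) and runs an end-to-end learning
check: 100 noise-free phantoms at 32³ (readers = 1 — with σ = 0 and no
mask jitter additional readers are exact duplicates), the micro profile
above, 10 epochs; the held-out split must reach ≥ 90% accuracy on both
refined heads. A second, reader-noise run (40 nodules × 4 readers,
σ = 0.7, jitter 1) probes whether the refined panel head beats the
refined individual head on panel labels; as analysed above, the ε = 0.6
cross-weighting makes the two heads' supervision nearly symmetric, and
at the default settings the result is a tie rather than a strict
ordering. These problem sizes were chosen as the smallest at which the
learning behaviour is meaningful.

## Known limitations

* The 4-subset individual-label design rotates the roles
  train/train/validation/test over the four subsets and averages over
  rotations; whether the source averaged this way is an interpretation.
* Readers who rated a nodule but drew no contour are assumed excluded.
* The LIDC-style XML writer emits per-slice boundary contours ordered by
  angle about the slice centroid — exact for the star-shaped phantom
  masks it serialises, not for arbitrary multi-component slices.
* Panel-label evaluation aggregates the refined panel probabilities by
  their mean across a nodule's annotations (threshold 0.5); majority
  vote is exposed as an alternative through the returned probabilities.
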