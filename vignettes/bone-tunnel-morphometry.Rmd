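---
title: "Methods: bone tunnel segmentation and trabecular morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bone tunnel segmentation and trabecular morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After anterior cruciate ligament reconstruction (ACLR) the tendon graft runs
through drilled femoral and tibial bone tunnels. These tunnels widen over
time, and the amount and quality of the trabecular bone that refills them is
a candidate marker of recovery. On high-resolution peripheral quantitative CT
(HR-pQCT; 0.0607 mm isotropic voxels for second-generation scanners, the
package default spacing) the tunnel cross-section appears as a low-density
region in each axial slice. tunnelmorph implements a two-stage analysis:

1. **Per-slice segmentation** of the tunnel cross-section with an
   encoder-decoder convolutional network trained under dice loss.
2. **3D morphometry**: the per-slice masks are stacked into a tunnel region
   of interest (ROI) and the standard trabecular indices are computed inside
   it -- BV/TV, Tb.Th, Tb.Sp, Tb.N, tunnel volume and the mean grayscale
   value (mGV).

Stacking is deliberately naive: slices are concatenated in order with no
inter-slice smoothing, since the annotation geometry is per-slice and any
smoothing would be an undocumented modelling step.

## The segmentation network

The encoder is the standard ResNet50 layout: a 7x7 stride-2 stem convolution
and 3x3 stride-2 max-pool, then four bottleneck stages (1x1/3x3/1x1 triples
repeated 3, 4, 6, 3 times; stride 2 entering stages 3-5), every convolution
followed by batch normalization and ReLU. Five downsampling steps take a
600x600x3 input to a 19x19x2048 bottleneck (`ceiling(600/32) = 19`); the
U-net-style decoder mirrors them with five nearest-neighbour upsamplings,
concatenating the encoder features at each resolution, and a final 1x1
convolution yields two class channels at the input size. A mask is obtained
by per-pixel argmax, which is identical to thresholding the foreground
softmax probability at 0.5; `predict_stack()` also exposes an explicit
probability threshold for users who want an asymmetric operating point.

The network, its minimal reverse-mode autodiff tape and the Adam optimizer
are implemented natively in R (convolutions evaluated as sums of
strided-slice matrix products, so the heavy lifting stays inside BLAS). The
implementation is verified by finite-difference gradient checks during
development and by the overfitting experiment in the test suite. Default
training configuration: 100 epochs, batch size 12, Adam with learning rate
1e-4, beta1 0.9, beta2 0.999, weight decay 1e-10, and a step-decay schedule
(x0.5 every 25 epochs). The schedule is the one genuinely open choice: only
"gradually decreasing" behaviour is required, and a documented fixed step
decay keeps runs reproducible. No data augmentation is applied by default.
Pretrained encoder weights are not bundled (the package ships as source text
only), so training always starts from seeded He-normal initialisation;
`train_config(pretrained_encoder = TRUE)` is rejected rather than silently
ignored.

A `variant = "reduced"` model (stage repeats 1,1,1,1; base width 8) keeps
the exact stride and shape contract of the full network while being small
enough to train in seconds on one CPU core. All training tests use it; the
shape and channel contract of the full-width network is still exercised
directly by a 600x600 forward pass.

`split_stratified()` reproduces the stratified train/validation protocol:
largest-remainder allocation per compartment keeps femur and tibia
proportions within one item of the whole-set proportions (e.g. a 1058-scan
set at fraction 793/1058 yields 793 training and 265 validation items).

## Segmentation scoring and agreement

`segmentation_scores()` computes precision, recall, IoU, pixel accuracy and
dice from the confusion counts. Empty-denominator conventions are
identity-consistent: if both masks are empty on a slice the pair scores 1,
if exactly one is empty the directional ratios score 0. `pairwise_agreement()`
evaluates every unordered pair of mask sources (network detections and any
number of annotators), macro-averaging per-slice metrics by default; whether
such published tables are macro- or micro-averaged is usually unstated, so
both poolings are exposed (`pooling = "macro"|"micro"`). The mGV of a
sequence is the unweighted mean of per-slice means ("mGV across all
slices"); a voxel-weighted variant is available since the two differ
whenever the tunnel cross-section area varies along the tunnel.

## Morphometry

* **BV/TV** is the exact voxel-count ratio of thresholded bone to tunnel
  ROI. The bone threshold inside the tunnel is Otsu's method on the
  tunnel-interior intensities by default (deterministic, parameter-free, no
  calibration needed); a fixed intensity can be supplied.
* **Tb.Th / Tb.Sp** are volume-weighted means of Hildebrand-Rueegsegger
  local thickness maps of the bone and non-bone phases: the value at a voxel
  is the diameter of the largest sphere fully contained in the phase that
  covers the voxel. Implementation: exact 3D squared Euclidean distance
  transform (Felzenszwalb-Huttenlocher separable scans) followed by
  maximal-sphere painting, in compiled code. The inscribed radius uses a
  half-voxel boundary correction (`sqrt(EDT^2) - 0.5` voxels), which makes a
  1-voxel feature measure one voxel and an odd-width slab exact;
  even-width slabs are under-read by exactly one voxel layer. All reported
  thicknesses therefore carry a +/- 1 voxel discretisation error.
* **ROI convention.** Thickness maps are computed on whole-grid phase masks
  (same threshold) and then averaged over the tunnel interior, so inscribed
  spheres may extend past the ROI wall. Computing them on ROI-clipped
  phases instead would bias both indices low near the wall by up to the
  local feature size. Volume faces are open (structures touching a face are
  treated as continuing past it); analyses should either pad with
  background or, as the validation suite does, keep the ROI at least one
  structural period away from the faces.
* **Tb.N** has no universally stated definition in report-oriented tools.
  The default (`"direct"`) is the reciprocal of the mean mid-axis spacing of
  the bone phase, estimated as `1 / (Tb.Th + Tb.Sp)`; for a parallel-plate
  lattice this equals the true plate frequency `1/p` exactly. Two
  alternatives are exposed: the plate-model `BV/TV / Tb.Th` (identical to
  `1/p` on ideal plates) and `1 / Tb.Sp`, which is the relation that
  published per-tunnel tables in this application empirically track
  (separation dominates when BV/TV is low). None is claimed to replicate
  any specific third-party tool.
* **Volume** is exactly `voxel count * spacing^3`; **mGV** is the sequence
  mean grayscale under the mask.

Intensities are used as stored, with no Hounsfield or mineral-density
calibration; the package convention for fixtures and phantoms is an
8-bit-like 0-255 scale, which matches the magnitude of published tunnel mGV
values (~50-125). Spacing is a single isotropic scalar carried as metadata
and never inferred from file headers.

## The synthetic phantom

Real post-ACLR HR-pQCT scans with expert tunnel masks are not publicly
available, so validation rests on a parametric phantom
(`make_lattice_phantom()`): a parallel-plate lattice (bone where the
slice-axis position modulo `p` is below `t`) of bright voxels on a dark
background, optionally with Gaussian noise, and a slice-aligned cylindrical
tunnel carved out (`carve_tunnel()`), a seeded uniform fraction of which can
be refilled with bone to mimic early bone fill. Plates (rather than rods)
are the default because every index has a closed form
(`expected_lattice_metrics()`): BV/TV = t/p, Tb.Th = t, Tb.Sp = p - t,
Tb.N = 1/p. Phantom defaults (t = 0.12 mm, p = 0.45 mm, i.e. BV/TV ~ 0.27,
Tb.N ~ 2.2 /mm) sit in the normative range for peripheral cancellous bone at
HR-pQCT resolution; intensity levels 180/40 with noise SD 8 give the strong
bone/marrow contrast typical of these scans.

What the phantom does **not** emulate: curved or oblique tunnel axes (the
axis is slice-aligned, matching per-slice annotation geometry), cortical
bone, partial-volume blur, beam hardening and ring artifacts, and the
anatomical variability of real knees. Passing the phantom suites therefore
demonstrates correctness of the measurement chain, not clinical performance
of a trained network; headline validation scores on private clinical data
are out of reach of this package by construction.

`make_training_set()` turns the phantom into a seeded annotated corpus:
slices from lattices with jittered tunnel position and radius, paired with
ground-truth masks.

## Numerical and reproducibility choices

* All randomness (phantom noise, refill choice, jitter, weight
  initialisation, shuffling) flows from explicit integer seeds through a
  save/restore RNG helper, so library calls never disturb the caller's RNG
  stream; identical seeds give bit-identical volumes, splits and loss
  histories on one platform with single-threaded BLAS.
* Dice loss uses smoothing epsilon 1e-6; batch norm uses epsilon 1e-5 and
  momentum 0.1.
* Cohort summaries keep full precision; rounding (half away from zero, 3
  decimals for fractions/mm, 2 for Tb.N and mGV, whole mm3 for volume)
  happens only at report rendering. The default SD is the population
  (divide-by-n) convention, because the published per-tunnel worked-example
  cohort's +/- values follow it at every printed precision (the test suite
  verifies all seven checkable SDs); the sample convention is a switch.
  One-row groups report `NA` rather than a misleading 0.
* PNG masks store foreground as 255 and read any stored value >= 128 as
  foreground, so masks survive editors that perturb levels; NIfTI masks
  store 0/1. Both dialects round-trip exactly.

## Validation problem sizes

The shipped validation suite runs the full chain at desk scale: exhaustive
maximal-sphere oracles on grids up to 14-16 voxels per side, plate-phantom
recovery at spacing p/10 over three t/p ratios (BV/TV recovered within
0.02, Tb.Th and Tb.Sp within one voxel), a 600x600 forward pass of the
full-width network for the shape contract, and a 200-step overfit of the
reduced network on eight 48x48 phantom slices (training-set dice above
0.95, prediction IoU above 0.9). These sizes were chosen as the smallest
problems that still exercise every code path nondegenerately.

## Known limitations

* The thickness means inherit the +/- 1 voxel discretisation of the
  maximal-sphere method; indices of structures only 1-2 voxels thick are
  dominated by it.
* Otsu's threshold assumes a bimodal tunnel-interior histogram; in a tunnel
  that is almost entirely void (or entirely bone) a fixed threshold is the
  better choice, and the degenerate all-bone/all-void cases are handled by
  convention (Tb.Sp = 0 when no void exists in the ROI).
* Training the full-width network to clinical quality is outside the
  package's scope on CPU; the architecture is faithful, but users wanting
  production weights should export the design to a GPU framework and import
  the resulting masks for the morphometry stage.
* Anisotropic voxels, DICOM metadata and density calibration are
  unsupported by design.
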