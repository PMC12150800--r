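---
title: "Multi-output segmentation and quantification of small vessel disease markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-output segmentation and quantification of small vessel disease markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cerebral small vessel disease (CSVD) shows up on brain MRI as four distinct
lesion classes, each with its own defining contrast: white matter
hyperintensities (WMH, bright and confluent on FLAIR), cerebral microbleeds
(CMB, small dark foci on susceptibility-weighted imaging), lacunes
(CSF-like cavities with a bright FLAIR rim) and enlarged perivascular
spaces (EPVS, thin CSF-signal tubes best seen on T1). Clinical practice
grades each class on ordinal visual scales and sums presence points into a
0-4 total burden score; these scales are coarse, rater-dependent and blind
to volume. `csvdseg` implements an automated alternative: one multi-output
segmentation network covering all four markers across the three sequences,
followed by volumetric quantification and a cohort-standardized Z-score
burden.

## The network

The model, MO-UNet, is a U-shaped network with

* **one shared encoder** — a stem convolution plus one strided MBConv block
  per stage (depthwise separable 3x3 convolution, 1x1 pointwise
  convolution, Swish activations, residual connections whenever input and
  output shapes match). Every slice of every sequence passes through this
  encoder, so representations common to the sequences are learned from the
  pooled data;
* **a selection unit** — hard routing keyed on the batch's sequence tag:
  FLAIR feeds the WMH and lacune decoders, SWI the CMB decoder, T1 the
  EPVS and lacune decoders. Routing by metadata (rather than a learned
  gate) makes the unit deterministic and testable; which decoders exist
  and which sequences feed them is configuration, not code;
* **four marker-specific decoders** — per stage: nearest-neighbour 2x
  upsampling, concatenation with the encoder skip at that scale, a 3x3
  convolution with batch normalization and Swish, and a concurrent
  spatial/channel squeeze-and-excitation (scSE) block. Fusion of the two
  excitation branches is additive. A 1x1 convolution and sigmoid emit a
  probability map at input resolution.

The encoder can be pretrained as a plain reconstruction autoencoder
(decoder built from fractionally-strided transposed convolutions, MSE
loss) and its parameters transferred into the segmentation model. We
implement plain reconstruction rather than a contrastive objective: it is
the variant that is fully specified by an input/output pair, and the
pretraining path has a clean identity test (transferred encoders reproduce
their features exactly). A contrastive term could be added at the same
hook.

Training minimizes, per routed marker, the sum of pixelwise binary
cross-entropy and soft Dice loss,

$$L = L_{ce} + L_{Dice},\qquad
L_{Dice} = 1 - \frac{2\sum_i x_i y_i + s}{\sum_i x_i + \sum_i y_i + s},$$

with Adam, L2 weight decay $\lambda = 10^{-4}$, batch size 6 and the
learning-rate schedule $lr(t) = 0.001 \cdot 0.95^{t/500}$ with a
*continuous* exponent in the global step $t$ (the staircase reading of the
same formula is the other defensible choice; we implement the formula as
written). Early stopping monitors the mean validation Dice over the active
markers and stops after 5 epochs without improvement; the protocol leaves
the early-stopping metric open, and Dice is the quantity everything else
in the pipeline is judged by.

### Numerical choices

* Cross-entropy probabilities are clamped at `eps_clip = 1e-7`; Dice uses
  smoothing `s = 1`. Both are conventional stabilizers.
* "epsilon = 0.001 and momentum = 0.99" are interpreted as the batch
  normalization constants, not Adam's: Adam has no single momentum and its
  conventional epsilon is 1e-8, while those two values are exactly the
  common batch-norm settings.
* Each decoder head's bias starts at -4, the logit of a ~2% foreground
  prior. Starting at the class prior instead of p = 0.5 removes the long
  initial phase in which the network merely learns to predict background.
* Batch-norm running statistics are seeded from the first training batch
  and then follow the 0.99-momentum EMA. With a 0/1 initialization the EMA
  needs hundreds of steps to become usable, during which evaluation-mode
  forwards (and hence early stopping) are meaningless.
* Interpolation: bilinear for images, nearest for masks, zero padding for
  all geometric transforms; masks are re-binarized at 0.5 after every
  interpolation.
* Probability maps are binarized at 0.5 (configurable).

## The phantom generator

No imaging data accompanies the method, so the package ships a synthetic
multisequence phantom: co-registered T1/FLAIR/SWI grids (default
64 x 64 x 24 voxels at 3 x 3 x 5 mm; 320 x 320 works through the same
configuration) containing an ellipsoidal brain, a central ellipsoidal
ventricle surrogate and an interior basal-ganglia box. Lesion counts per
marker are drawn as Poisson(rate x (1 + burden)) for an ordinal burden
level 0-4 — stated explicitly so that count statistics have a testable
null. Geometry follows the lesion definitions: WMH are anisotropic blobs
(5-30 mm) confined to a periventricular shell, CMBs spheres (2-10 mm),
lacunes spheres (3-15 mm) with a one-voxel bright FLAIR rim, EPVS thin
cylinders (1-3 mm diameter, 3-20 mm long), half of them targeted at the
basal-ganglia box. Lesions are inserted only into the sequences where the
real lesion has contrast, are kept mutually non-adjacent (so connected
components equal inserted instances; every drawn lesion realizes at least
one voxel even when thinner than a voxel), and intensities are
piecewise-constant tissue classes plus i.i.d. Gaussian noise (default SD
5% of the dynamic range).

What the phantom does *not* emulate — and therefore what passing tests do
not show about hospital data: anatomy beyond the ellipsoid, partial-volume
effects, bias fields, inter-sequence misregistration, scanner or k-space
artefacts, and the intensity overlap between lesion classes that makes
real EPVS/lacune discrimination hard. Phantom Dice values are upper bounds
on clinical performance, not estimates of it. Counts can fall below the
Poisson draw at extreme crowding (placement retries are capped), which
slightly flattens — but does not invert — the burden trend.

## Preprocessing and data handling

Volumes are read from NIfTI with their header spacing (a missing or
non-positive spacing is an error, and a DICOM directory is refused rather
than silently gap-filled: no DICOM reader is available to R in this
build). Slices are resized (bilinear; masks nearest) and min-max
normalized to [0, 1] *per slice* — slice and volume scope are both
defensible, and per-slice is chosen because the network consumes 2D
slices. Positive slices are expanded exactly 11-fold: original, vertical
and horizontal flips, rotations of +/-30 degrees, displacements of +/-20%
along each in-plane axis, and scalings by 0.8 and 1.2. The expansion
factor of 11 is a protocol constant; this inventory realizes it exactly
with the three standard transform categories (flips, rotations and
displacements, scalings). The cross-validation plan is
patient-stratified: 5 folds as equal as possible, and for each held-out
fold an 80:20 train/validation split of the remainder
(`round(0.2 * 84) = 17` validation patients for a 105-patient cohort).

## Evaluation

Voxelwise precision, specificity and Dice come from the confusion matrix
(`Pre = TP/(TP+FP)`, `Sp = TN/(FP+TN)`, `Dice = 2TP/(FP+2TP+FN)`), per
patient volume (per-slice averaging is the other possible reading; the
per-volume choice is flagged in the function help). HD95 is the 95th
percentile of the pooled directed surface distances in mm; the
`scaled_max` variant (0.95 times the larger directed Hausdorff distance)
is kept behind a flag because the printed formula and the prose definition
of HD95 disagree, and the prose is the standard definition. Empty masks
yield a missing HD95, never 0. Lesion-wise sensitivity uses
26-connectivity components and a boundary-inclusive 50% coverage rule; WMH
is excluded (confluent lesions are not countable objects). Confidence
intervals are percentile bootstraps over patients.

Burden quantification: marker volume = foreground voxels x voxel volume;
visual-score bins (CMB 0 / 1-10 / >10, lacunes 0 / 1-4 / >4, basal-ganglia
EPVS 0 / 1-10 / 11-20 / 21-40 / >40, WMH grade from the summed Fazekas
scales) — the top EPVS bin is read as ">40", treating the printed "4 = 40"
as a truncation; the 0-4 total burden score (one point each for lacune
presence, CMB presence, EPVS bin >= 2, and WMH severity — deep Fazekas >= 2
or periventricular grade 3 when the separate grades exist, else the
summed-grade surrogate, configurable because phantoms carry no true
Fazekas reading); and per-marker cohort Z scores (sample SD) summed into
`z_sum`. Agreement statistics are Pearson correlation, Bland-Altman limits
and one-way ANOVA with uncorrected LSD pairwise comparisons, as the
procedure specifies.

## Desk-scale study

`run_desk_study()` is the package's end-to-end demonstration and the basis
of its acceptance checks: 30 phantoms at 64 x 64 x 24, stage widths
8-16-32, burden-stratified patient-level train/validation/test split
(20/5/5), 10 autoencoder epochs, then at most 30 training epochs on the
FLAIR route (WMH + lacune decoders; up to 240 training slices). These
sizes keep the whole study at a few minutes on one CPU core. The held-out
Dice is pooled over the test patients' voxels. Expect WMH Dice well above
0.6, predicted-vs-true WMH volume correlation above 0.9, and mean `z_sum`
increasing across the five generated burden levels. The `z_sum` trend is
strictly monotone in expectation (the suite verifies volume monotonicity
over 100 seeds); with only six patients per level a single cohort can tie
adjacent levels:

```{r}
library(csvdseg)
st <- run_desk_study(seed = 1)
st$test_dice
st$agreement$WMH$pearson
st$z_sum_by_level
```

## Known limitations

* The network stack (convolutions, backprop, Adam) is implemented in
  R/C++ within the package and is sized for desk-scale experiments; the
  architecture supports 320 x 320 inputs and deeper stages, but full-scale
  training is out of scope.
* 2D (slice-wise) segmentation only; no 3D convolution variant.
* The selection unit is hard metadata routing; it does not learn to mix
  features across decoders when a sequence feeds several markers.
* Phantom realism limits, as above; no claim about clinical performance is
  made or tested.
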