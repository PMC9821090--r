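---
title: "Morphological FAZ extraction from en face OCTA: methods and design"
author: "fazkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological FAZ extraction from en face OCTA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fazkit)
```

## The problem

The foveal avascular zone (FAZ) is the capillary-free region at the center
of the macula. Its area and shape are clinical biomarkers, measurable
non-invasively on en face OCTA projections of the superficial retinal
layer: a bright capillary network on a dark background with a dark central
region of roughly 0.04--1.0 mm^2 (healthy eyes cluster near 0.25--0.3
mm^2). Manual tracing of the FAZ boundary is the accuracy reference but is
slow and burdens any attempt to build large labelled datasets for training
segmentation networks. `fazkit` implements an automatic morphological
extraction pipeline, the batch machinery that turns extractions into
amplified binary-label training datasets, a synthetic scene generator with
exact ground truth, and the agreement statistics used to compare extraction
methods.

## The extraction pipeline

`extractFaz()` composes six deterministic stages:

1. **Bandpass denoising** (`fftBandpass`): a frequency-domain
   difference-of-Gaussians filter passes structures between `filterSmall`
   (3.5 px) and `filterLarge` (1024 px). Its main job on this imagery is
   removing sub-capillary-scale bright specks -- the high-luminance noise
   that plagues high-brightness captures -- while leaving the vessel
   network untouched. The result is contrast-autoscaled with
   `saturationTolerance` (5%) of pixels saturated.
2. **Binarization** (`binarizeVasculature`): a global histogram threshold
   (iterative intermeans, "isodata"; Otsu selectable) labels bright pixels
   as vessel signal.
3. **Gap bridging** (`closeVesselGaps`): `nDilate` (10) iterations of 3x3
   binary dilation connect interruptions in the capillary signal up to
   about `2 nDilate` px across, so the avascular center becomes a closed
   hole in the vessel mask.
4. **Avascular recovery** (`recoverFazRegion`): `nErode` (10) matched 3x3
   erosions shrink the vessels back; the complement of the eroded mask is
   the avascular field. Dilation followed by matched erosion is a
   morphological closing: gaps stay bridged while the FAZ regains its
   original footprint up to boundary-curvature effects.
5. **Particle selection** (`selectFazComponent`): connected components
   (8-connectivity) of the avascular field are size-gated to
   `[particleMinPx, particleMaxPx]` = [5000, 120000] px at the native
   1024 x 1024 scale -- bracketing the physiologic FAZ area range at
   3/1024 mm/px -- and the surviving component whose centroid lies nearest
   the image center is kept, holes filled.
6. **Enlargement** (`enlargeRegion`): the selected region grows by
   `enlargePx` (4) px of Euclidean distance. Binarization places the
   avascular boundary at the inner edge of the surrounding capillaries;
   the enlargement compensates that half-vessel-width bias, matching where
   a human tracer draws the boundary (through the capillary ring).

All counts and gates are exposed in `ksmParams()`; adjusting `nDilate` /
`nErode` is the recommended remedy when extraction fails on unusually
noisy or low-signal images, since the defaults trade gap bridging against
erosion of true FAZ boundary detail.

### Assumptions

The pipeline assumes a single macular-centered avascular region on a
roughly uniform-brightness field: it is a *healthy-eye* tool. Enlarged
foveae, capillary dropout from retinopathy, or off-center scans violate
the centroid-nearest-center selection rule and the size gate.

## Conventions and numerical choices

* **Coordinates** are 0-based `(row, col)` with pixel centers at integer
  coordinates, stated once and used everywhere.
* **Rasterization** (`polygonToMask`) uses the even-odd rule sampled at
  pixel centers; a center exactly on the boundary is foreground.
  `maskToPolygon` traces the boundary along pixel *edges* (vertices at
  half-integer coordinates), so polygon round trips are exact -- a useful
  property for ROI archival.
* **Morphology borders**: out-of-frame samples replicate the nearest
  frame pixel. Consequently an all-foreground mask is a fixed point of
  erosion, and a fully vascularized image yields an empty avascular field
  rather than a spurious border rim.
* **8-connectivity** labeling is assembled from 4-connected labeling plus
  a union-find merge of diagonally touching labels.
* **Enlargement** thresholds an exact Euclidean distance map rather than
  iterating 3x3 dilations (which would give square Chebyshev corners);
  enlarging a single pixel by 4 yields the 49-point digital disk.
* **FFT padding**: images are mirror-padded into a square power-of-two
  frame at least 1.5x the larger side, so borders see a seamless
  reflection instead of wrap-around that would fabricate vessel signal at
  the frame edge. Gaussian cutoffs sit at half amplitude at the named
  structure size; the filter is specified by band behavior, not by bit
  equality with any particular desktop implementation.
* **Autoscale degeneracy**: a constant image is returned unchanged; when
  clipping collapses the range (constant central mass with outliers) the
  clipped values map to 0.
* **Ties** in component selection break by centroid-to-center distance,
  then larger area, then lower label index -- a total order, so extraction
  is reproducible byte-for-byte.
* **16-bit inputs** are linearly min-max rescaled to 0--255; multi-channel
  inputs collapse by standard luminance weights.

## The synthetic scene generator

`renderScene()` emulates what the pipeline actually relies on, not retinal
hemodynamics: a bright capillary network (procedural quadratic-Bezier
strokes of 1--5 px width) covering `vesselDensity` (0.35) of the frame, a
terminal-capillary ring straddling the ground-truth FAZ boundary with
segment dropouts at `gapRate` (0.15) emulating vessel-signal
interruptions, multiplicative log-normal speckle (`noiseSigma` 0.15, the
signal-dependent noise character of coherent imaging), and an optional
high-brightness variant. The ground-truth shape is a star-convex radial
harmonic perturbation of a circle (`fazIrregularity` 0.15 gives the mild
lobulation of real FAZ boundaries), iteratively rescaled until its pixel
area matches `fazAreaMm2` (0.27 mm^2, the healthy-eye regime) within 2%.
Scenes default to the native acquisition geometry: 1024 px over a 3 mm
field.

Speckle is applied to the *acquired* signal, after the brightness
transform: a lifted background carries proportionally larger excursions.
The `"bright"` preset (`brightnessShift` 60 with contrast compression to
55% about the scene mean) therefore produces both the displaced, flattened
histogram of a high-brightness capture and its characteristic failure
mode -- isolated background speckle excursions that cross the vessel
threshold as 1--2 px bright specks. Those specks are exactly what the
bandpass stage removes; without it they survive binarization, are welded
into a solid mass by the dilations, and destroy the avascular region.
The acceptance suite asserts the direction of that effect (bandpass
strictly improves mean recovery on bright scenes), which the generator is
designed to express, not its magnitude on real data.

What the generator does **not** emulate: perfused-capillary texture
inside vessels, projection artifacts from deeper plexuses, motion-line
artifacts, pathology (enlarged or fragmented FAZ), or device-specific
noise spectra. Passing the synthetic recovery suite therefore shows the
pipeline is correctly assembled and robust to the modeled failure modes;
it does not certify accuracy on any particular device's images.

## Evaluation machinery

Agreement between methods uses pixel-count set arithmetic on
geometry-reconciled masks (nearest-neighbour resampling of the larger
grid onto the smaller):

* Jaccard `J = |A&B| / |A or B|`, Dice `DSC = 2|A&B| / (|A|+|B|)`; the
  identity `DSC = 2J/(1+J)` holds per record and is fuzz-tested to 1e-9.
* False negatives / false positives are normalized by the **union**:
  `FN% + FP% = (1-J)*100` exactly. Union normalization was chosen over
  per-mask normalization because it yields that clean identity linking
  the excess/deficiency table to the similarity table.
* Areas are `pixels * mmPerPixel^2`, optionally scaled by
  `(axialLength / reference)^2` with a configurable 24.2 mm reference --
  a squared axial-length ratio stands in for full Littmann--Bennett
  telecentric correction, and the factor is reported separately so exact
  coefficients can be substituted.
* Per-subject between-method variability is `100 * SD / mean` of the
  areas (sample SD).
* The comparison battery is nonparametric throughout: Shapiro--Wilk per
  condition (reported, not used to switch tests), Friedman across
  conditions, pairwise paired Wilcoxon signed-rank post-hocs with
  Bonferroni adjustment (`p_adj = min(1, m*p)`), Spearman rank
  correlation of areas per pair. Degenerate inputs (identical columns)
  short-circuit to statistic 0 / p 1 rather than erroring, so an
  all-methods-agree comparison is representable.

## The annotation factory

`processStack()` extracts in stable order, in chunks of 5 by default --
the cadence at which a human can confirm a batch before ROIs are
committed; confirmation is an optional hook, and failures are collected
per image rather than aborting the batch. `makeLabelImage()` produces the
0/255 label rasters; `amplifyDataset()` applies flips and quarter/half
turns identically to image and label (k transforms multiply the pair
count by 1+k); `exportTrainingSet()` resizes 1024 to 512 px by
nearest-neighbour sampling (interpolation "none", keeping labels strictly
binary) and crops to 256 px. The crop default is `"center"` -- it keeps
the fovea, which is where the region of interest always is -- with
`"fourtile"` available when data volume matters more than centering.

## Problem sizes

The test suite exercises morphology against brute-force per-pixel oracles
on 100 random 32 x 32 masks, metric identities on 1000 random pairs,
recovery on twenty 1024 px default scenes plus ten high-brightness pairs,
and the null calibration of the rank battery on 200 simulated 40-eye
cohorts; `scripts/acceptance.R` recomputes the same quantities from
scratch at those sizes. Unit tests use 256--512 px scenes where full
resolution adds nothing to the property under test.

## Known limitations

* Healthy-eye geometry is assumed (central, size-gated FAZ).
* The bandpass is specified by band behavior; other implementations of
  the same nominal filter differ in windowing and will not agree
  bit-for-bit.
* The magnification correction is the squared axial-length ratio, not a
  full eye-model correction.
* ROI serialization is a documented JSON schema; binary ROI formats of
  desktop tools are out of scope, as are proprietary OCTA raw files.
* Mask-to-polygon tracing represents the outer boundary only; masks with
  interior holes should be filled first.
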