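# fazkit

Automatic extraction of the **foveal avascular zone (FAZ)** from en face
OCTA images, and everything needed to turn those extractions into labelled
training data and to evaluate how well extraction methods agree.

The FAZ — the capillary-free region at the center of the macula — is a
clinical biomarker whose area and shape are measured on en face OCTA
projections of the superficial retinal layer (typically a 3 mm × 3 mm
macular field exported at 1024 × 1024 px). Manual boundary tracing is the
accuracy reference but makes annotating training datasets for
segmentation networks prohibitively slow. `fazkit` is aimed at
researchers who want a deterministic, tunable automatic extractor and a
reproducible agreement-evaluation workflow.

## The algorithm

`extractFaz()` is a morphological pipeline over a binarized vessel mask
*V*:

1. **Bandpass denoise** the image: a frequency-domain
   difference-of-Gaussians passing structure sizes in
   (`filter_small` = 3.5 px, `filter_large` = 1024 px), removing the
   sub-capillary bright specks that break thresholding on
   high-brightness captures; autoscale with 5 % saturation.
2. **Binarize** by a global isodata (iterative-intermeans) threshold:
   *V* = bright vessel signal.
3. **Close capillary gaps**: *V* ← *V* ⊕ B₃ (3×3 dilation), iterated
   `n_dilate` = 10 times, bridging vessel-signal interruptions.
4. **Recover the avascular field**: complement of *V* ⊖ B₃ iterated
   `n_erode` = 10 times (a morphological closing, seen from the
   background).
5. **Particle analysis**: 8-connected components size-gated to
   [5000, 120000] px (at 1024² scale); keep the component whose centroid
   is nearest the image center; fill holes.
6. **Enlarge** by 4 px of Euclidean distance (distance-map thresholding),
   compensating the half-vessel-width bias of thresholding so the
   boundary lands where a human tracer draws it.

Agreement between two masks *A*, *B* is quantified by pixel counts:
Jaccard *J* = |A∩B| / |A∪B|, Dice *DSC* = 2|A∩B| / (|A|+|B|),
FN% = 100·|A∖B| / |A∪B|, FP% = 100·|B∖A| / |A∪B| (so
FN% + FP% = (1−J)·100), areas as pixels·(mm/px)², optionally scaled by a
squared axial-length ratio, and a nonparametric comparison battery
(Friedman, pairwise Wilcoxon signed-rank with Bonferroni, Spearman).

A synthetic OCTA scene generator (`renderScene()`) provides images with
exact ground truth — procedural capillary strokes, a terminal-capillary
ring with seeded dropouts, multiplicative speckle, and a high-brightness
preset — so the full pipeline is testable without clinical data.

## Worked example

```r
library(fazkit)

scene <- renderScene(syntheticSpec(seed = 7))   # 1024 px, 3 mm field
scene
#> SyntheticScene 1024 px, truth FAZ 0.2708 mm^2 (target 0.27), seed 7

res <- extractFaz(sceneImage(scene))
res
#> FazResult: 32342 px, 0.2776 mm^2  eye: synth0007

jaccardIndex(fazMask(res), truthMask(scene))    # 0.976
diceCoefficient(fazMask(res), truthMask(scene)) # 0.988
fnFpRates(truthMask(scene), fazMask(res))       # FN 0.00%  FP 2.43%

correctedArea(fazMask(res), axialLengthMm = 24.8)
#> $areaMm2 0.2915   $factor 1.0502
```

The extracted 0.2776 mm² sits just above the 0.2708 mm² truth — the
4-px enlargement deliberately overshoots the inner-capillary boundary to
match manual tracing convention — giving Jaccard 0.976 ("excellent" is
conventionally ≥ 0.9), all of the residual being false-positive rim.

Batch annotation and evaluation have the same shape:

```r
batch <- processStack(images, chunkSize = 5)             # per-image FazResults
pairs <- amplifyDataset(pairs, c("fliph", "rot90"))      # x(1+k) pairs
exportTrainingSet(pairs, "out/", resizeTo = 512, cropTo = 256)
compareMethods(list(ksm = ..., manual1 = ..., manual2 = ...))
```

A thin command-line front end covers the same operations:
`inst/exec/fazkit <extract|synth|dataset|eval> [options]`.

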