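# blastseg

Detection of Acute Lymphoblastic Leukemia (ALL) blast cells in stained
peripheral blood-smear micrographs, using classical image processing only —
no training data, no learned models. The package is aimed at people
building or evaluating lightweight screening tools for microscopy: it
segments candidate blasts, classifies each image as cancerous or
non-cancerous, and scores predictions with standard confusion-matrix
metrics. A deterministic synthetic smear generator with per-image ground
truth makes the whole pipeline testable without clinical images.

## The method

In a Romanowsky-stained smear (Giemsa, Leishman), blast nuclei stain a
deep violet/purple while erythrocytes are pink-red and the background is
pale. The pipeline exploits exactly that color contrast:

1. **Gaussian blur** — each channel is convolved with the separable 1-D
   kernel `g(x) = exp(-x² / 2σ²) / √(2πσ²)` horizontally then vertically
   (default σ = 2 px, radius ⌈3σ⌉), suppressing stain noise and specular
   reflections.
2. **RGB → HSV** — per pixel, with `max`/`min` the channel extremes:
   `H = (G−B)/(max−min)` if the maximum is R, `2 + (B−R)/(max−min)` if G,
   `4 + (R−G)/(max−min)` if B; negative values wrap by +6, scaled by 60 to
   degrees (red 0°, green 120°, blue 240°). Achromatic pixels get hue 0,
   saturation 0.
3. **Hue mask** — pixels with hue in `[L_b, U_b]` (default 250–340°, the
   violet band) and saturation ≥ 0.25, value ≥ 0.15 become white (255).
4. **Morphological opening** — erosion then dilation with a 5 × 5
   structuring element removes small white specks and smooths edges.
5. **Binary threshold** (midtone 127 / white 255) and **bitwise AND** with
   the original frame produce the segmented image.
6. **Contours** — each 8-connected white region is boundary-traced; regions
   smaller than 0.1 % of the frame are dropped; contours are drawn in green
   on both the original and the segmented image.

An image is called **cancerous** when at least one contour reaches the
minimum blast area (by default, any surviving contour). Predictions against
known labels yield TP/FP/TN/FN and the five measures: accuracy, precision,
recall (sensitivity), specificity and F-measure.

## Worked example

```r
library(blastseg)

smear <- generate_smear(scene_spec(n_blasts = 2, seed = 7))
res <- run_pipeline(smear$image)
res
#> <segmentation_result> 256 x 256 frame, 2 contour(s)
#>   areas (px^2): 4129, 3151

classify(res, image_id = "Im007_1")
#> <prediction> Im007_1: cancerous (2 contour(s), largest 4129 px^2)
```

Both generated blasts are recovered as contours of ~4100 and ~3200 px²
(consistent with their 22–40 px radii), and the presence of a
sufficiently large contour drives the positive call. A full synthetic
evaluation — 20 positive and 20 negative scenes, scored against the
generator's ground-truth labels:

```r
d <- file.path(tempdir(), "demo")
generate_dataset(20, 20, d, seed = 42)
ev <- evaluate_dataset(d)
ev$metrics
#> Performance measures
#>   Accuracy         95.00%
#>   Precision score  90.91%
#>   Recall Score     100.00%
#>   Specificity      90.00%
#>   F-measure        95.24%
```

Every blast-bearing image is detected (recall 100 %); two negatives are
falsely flagged where strongly pink erythrocytes blend into the pale
background and transiently enter the violet hue band — the same failure
mode the method shows on real non-blast material.

The same operations are available from a shell via the launcher in
`inst/cli/` (`segment`, `classify`, `evaluate`, `generate`, `metrics`);
for instance `blastseg metrics --tp 40 --fp 3 --tn 38 --fn 0` prints the
measures for a published confusion matrix.

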