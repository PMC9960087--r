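---
title: "Hue-band segmentation of leukemic blasts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hue-band segmentation of leukemic blasts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastseg)
```

## The problem and the model

Acute Lymphoblastic Leukemia floods the peripheral blood with immature
lymphoid blasts. On a Romanowsky-stained smear these cells are
conspicuous to a trained eye: large, with a violet/purple nucleus, an
irregular nuclear envelope, and vacuolated cytoplasm, against a field of
pink-red erythrocytes on a pale background. `blastseg` operationalizes
that visual cue as a pure color-segmentation problem: *a blast is a
sufficiently large, sufficiently saturated patch of violet hue*. There is
no learned component; the "model" is the composition of classical
operators and the assumptions are explicit:

* stain chemistry places blast nuclei in a narrow hue band that neither
  erythrocytes, eosinophil granules, nor background enter;
* blur removes noise at a scale well below the blast diameter, so
  denoising does not erase the signal;
* any region of in-band color larger than the area floor is blast
  material — the pipeline cannot distinguish other strongly
  basophilic-staining objects (e.g. dense lymphocyte nuclei) from blasts.

The processing order is fixed: bounded resize, hole filling, separable
Gaussian blur, RGB→HSV, hue-band mask, 5×5 opening, binary threshold,
bitwise AND with the original frame, contour extraction with an area
filter, contour drawing. Contours are computed after thresholding and
masking, never on raw color planes.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `sigma` | 2 | px | Stain grain and specular spots are 1–5 px; blasts are ≥ 40 px across, so σ = 2 denoises without merging cells. |
| `kernel_radius` | `ceiling(3*sigma)` | px | 3σ support carries > 99 % of the kernel mass. |
| `hue_lower`, `hue_upper` | 250, 340 | degrees | The violet/purple of Romanowsky-stained nuclear chromatin. Red (≈ 0°/360°) and orange eosinophil granules (20–40°) fall outside. |
| `sat_min` | 0.25 | – | Excludes the pale, near-achromatic background whose hue is numerically arbitrary. |
| `val_min` | 0.15 | – | Excludes near-black pixels whose hue is unstable. |
| `se_size` | 5 | px | Removes specks the opening cannot fit; anything ≤ ~4 px wide disappears. |
| `threshold_lo` | 127 | intensity | Midtone/white convention for binarizing the mask; strictly-greater comparison, so 127 itself maps to black. |
| `min_area_frac` | 0.001 | fraction of H·W | Residual debris after opening is still far smaller than a blast (≥ ~1000 px² at default scales). |
| `resize_max` | 1024 | px | Display-window bound; downscale only, bilinear. |
| `min_blast_area` (classifier) | pipeline floor | px² | Default makes the call "any contour present"; raising it discounts small contoured distractors such as eosinophils without re-segmenting. |

## Numerical choices

* **Threshold inequality.** Strict `> lo`: 126/127/128 map to 0/0/255.
* **Rounding.** Channel outputs round half-away-from-zero, then clip to
  [0, 255], once per operator. Printed percentages use the same
  half-away-from-zero rule at two decimals.
* **Borders.** Convolution replicates the edge pixel; zero padding would
  darken the rim and leak false hues into the mask. Morphology treats
  out-of-image pixels as background, so an element never "fits" over the
  border — an all-white mask erodes to a white interior with a
  `(size-1)/2`-pixel black frame. A consequence worth knowing: the
  erosion/dilation duality `δ(m) = ¬ε(¬m)` is exact only when the
  complement is taken on a background-padded embedding of the mask; taken
  naively on the finite frame, the two sides disagree on the border ring.
  The test suite checks duality in the padded form, where it holds
  bitwise.
* **Hue conventions.** Hue is stored in degrees `[0, 360)`; the negative
  branch of the hexcone formula wraps by +6 before scaling. Achromatic
  pixels get hue 0 *and* saturation 0, so any positive `sat_min` excludes
  them deterministically. The 8-bit export multiplies hue by 0.5 (0–179),
  the common byte packing.
* **Contours.** Components are 8-connected (background 4-connected);
  boundaries are Moore-neighbor traces, clockwise, starting at the
  topmost-leftmost pixel. Sorting is by area descending with
  (top, left) tie-breaks. Area is the component pixel count, not the
  polygon area of the trace. Single-pixel and two-pixel components yield
  degenerate traces (< 3 points); the default area filter removes them
  long before they matter.
* **Degenerate inputs.** An all-one-color frame produces an empty mask,
  zero contours, and a fully black segmented image — the correct negative
  call. Empty images and malformed arrays error early with explicit
  messages.

## Open design points, and the choices made

* **Hue bounds are nowhere specified numerically** in the source
  description of the method; 250–340° with the saturation/value floors is
  a stain-knowledge default, and every bound is configurable
  (`pipeline_config`, YAML files, CLI flags).
* **"Fill unfilled pixels"** is named but not defined by the method's
  description. Implemented as: a pure-black pixel whose 8-neighborhood is
  mostly (≥ 5 of the available neighbors) non-black is a hole and takes
  the per-channel median of its non-black neighbors, computed on the
  input so fill order is irrelevant.
* **One dilation or two.** The opening already ends in a dilation; the
  pipeline adds no extra dilation by default, with `extra_dilate = TRUE`
  available for the alternative reading.
* **The eosinophil rule.** Contoured eosinophils can appear in negative
  images without flipping the image-level call in the source method, by a
  mechanism it never formalizes. Here the classifier's `min_blast_area`
  is that mechanism, explicit and documented.
* **Internally inconsistent published metrics.** The published 2×2 counts
  for the 81-image private set (TP 40, FP 3, TN 38, FN 0) imply
  specificity 38/41 = 92.68 % and precision 40/43 = 93.02 %, yet 100 %
  and 93.20 % were printed; similarly the ALL-IDB1 counts imply recall
  93.88 % and specificity 96.67 % against printed 87.75 % / 95.81 %.
  `compute_metrics` reports what the counts imply, always; the test suite
  pins the computed 92.68 % so the divergence is documented in code.

## What the synthetic generator emulates — and what it does not

`generate_smear` paints: a pale faintly-lavender background with gentle
illumination drift; 35 anti-aliased erythrocyte discs (hue wrapping
340–20°, central pallor); optional orange granular eosinophils (20–40°);
blasts as radially perturbed discs (3–7 sinusoidal harmonics on the
radius, honoring the irregular nuclear envelope) with darker chromatin
speckle, hue 260–320°, radius 22–40 px; near-white specular spots;
additive Gaussian noise (σ = 3 levels). Scenes are 256 × 256 and bitwise
reproducible from the seed; the ground truth is the union of blast
interiors plus the image-level label.

These defaults were chosen once, as a plausible stained-smear
phenomenology, and define the package's standard test conditions. On the
fixed-seed 20 + 20 dataset the default pipeline reaches sensitivity 1.00
and specificity 0.90; the false positives arise where a strongly pink
erythrocyte blends into the pale background and the mixed hues transit
the 340° band edge at sufficient saturation — a realistic analogue of the
method's false positives on non-blast material.

What the generator does **not** model: touching/overlapping leukocytes,
platelets and smudge cells, staining batch variation, chromatic aberration
and uneven focus, nucleus/cytoplasm structure within blasts. Passing the
synthetic suite therefore demonstrates that the *operators and their
composition* behave as specified under the stated color phenomenology; it
does not certify clinical performance on real smears, which depends on
stain quality and on hue-band calibration to the local protocol.

## Problem sizes and runtime

The test suite and the reproduction script run at deliberately moderate
scale: 256 × 256 scenes, 40-image evaluation sets, 50 random 64 × 64
images for the convolution oracle, and 100 random 32 × 32 masks for the
contour oracle — together a sub-minute run on a single core, while still
exercising every operator at realistic cell scales.

## Known limitations

* Color is the only feature: hypogranular or atypically stained blasts
  outside the hue band are invisible, and any large violet object is a
  blast to this pipeline.
* The area floor is relative to frame size; extreme magnification changes
  require re-tuning `min_area_frac`.
* Contour tracing returns outer boundaries only; internal vacuoles are
  deliberately ignored.
* JPEG input requires EBImage; BMP is not supported.
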