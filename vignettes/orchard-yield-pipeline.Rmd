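---
title: "From top-view orchard imagery to yield maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From top-view orchard imagery to yield maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orchardyield)
```

## The problem

A grower wants, before harvest, a map of how many apples hang on each tree
and in each row. Nadir (straight-down) UAV imagery over an orchard can be
assembled into a georeferenced orthomosaic, and with per-tree GNSS
coordinates each tree's canopy can be cropped out and handed to a fruit
detector. Two obstacles separate detector output from a yield map:

1. **Only part of the crop is visible from above.** Canopies hide most
   middle- and underside-stratum fruit, so detected counts must be
   extrapolated to totals via a calibration against harvested or
   field-counted reference trees.
2. **Detector quality must be quantified** per picture — precision, recall,
   F1 and count accuracy against manually annotated ground truth — before
   anyone should trust the map.

`orchardyield` implements the full chain as testable parts: a synthetic
scene generator with exact ground truth, geodata primitives (affine
transforms, circular masks, raster/vector I/O), PASCAL VOC annotation
handling with tiling and augmentation, a detector contract with a
deterministic reference detector, the evaluation metrics, the calibration
regression, and the two map layers.

## The statistical model behind the generator

The generator is not a renderer of pretty pictures; it encodes the field
model the rest of the package is tested against.

**Layout.** Trees sit on a regular grid: `n_rows` rows spaced
`inter_row_m` apart, `trees_per_row` trees spaced `intra_row_m` within a
row, rotated by a compass bearing. Defaults (14 rows x 41 trees at 3 x 1 m)
reproduce a commercial high-density planting of roughly 0.4 ha.
Pollinator trees interleaved in real plantings are not modelled; the grid
count is the product of the two dimensions.

**Per-tree totals.** A published survey of 19 trees in this layout reports
per-tree totals with mean 255.16 and a printed narrative range of 175-308.
Only min, max and mean are available, so totals are drawn from a discrete
uniform distribution. A uniform on (175, 308) would have mean 241.5; since
the mean and the maximum are the better-attested quantities, the default
range is recentred to (202, 308), giving mean 255 — the minimum is the
least-constrained end. (The survey's own largest printed tree actually
sums to 319; see *Known inconsistencies* below.)

**Canopy strata.** Each total is split across top / middle / underside
strata. Mean fractions default to (27.31, 37.63, 35.06)% — the survey's
column averages. Per-tree scatter follows a Dirichlet distribution whose
concentration (default 40) was moment-matched to the survey's per-tree
spread of top-stratum percentages (≈ 7 points sd:
`0.2731 * 0.7269 / (c + 1) = 0.07^2` gives `c ≈ 40`). Fractions are
converted to integers summing exactly to the total by largest-remainder
apportionment — deterministic, sum-exact, ties broken by stratum order.

**Visibility.** Each fruit is independently visible from above with a
per-stratum probability, default (0.9, 0.3, 0): top fruit nearly always
visible, middle fruit occasionally through gaps, underside never. The
implied expected visible fraction is
`0.9 * 0.2731 + 0.3 * 0.3763 ≈ 0.359`, consistent with reports that well
under half of a tree's crop shows in nadir views.

**Rendering.** The scene rasterizes at a configurable ground sample
distance (default 4.18 mm/px, the resolution of the motivating survey's
orthomosaic) with a soil background, one green canopy disk per tree and one
red disk per *visible* fruit, plus optional Gaussian pixel noise
(`noise_sd`, default 2 grey levels). Every visible fruit contributes
exactly one ground-truth box: the tight pixel bounding box of its rendered
disk. Fruits may overlap (they do in real canopies); for tests that need
separable objects, `min_separation_m` enforces a minimum center distance by
rejection sampling. A pixel budget guard refuses accidental full-field
renders at 4.18 mm/px (≈ 10^8 px); desk-scale work uses a coarser GSD
(tests use 10 mm/px).

What the generator deliberately does **not** emulate: photorealistic
texture, foliage occlusion geometry, illumination gradients, rolling-shutter
distortion, or photogrammetric stitching artifacts. Consequently a perfect
score on clean synthetic scenes certifies the *pipeline* — geometry,
bookkeeping, matching, counting, calibration — not real-world detector
accuracy.

## Geodata conventions

* Continuous pixel coordinates are 0-based with (0,0) the outer corner of
  the top-left pixel; pixel centers sit at half-integers. Affines are
  shear-free and north-up (world y decreases with pixel row); the
  world/pixel round-trip is exact to well below 1e-9 m.
* Circular tree masks (default diameter 1 m, sitting inside the canopy and
  avoiding its edges) use pixel-center containment — a pixel belongs to the
  circle iff its center does, the common zonal-statistics rule. Out-of-mask
  pixels are blacked out, so tile content is exactly the masked canopy.
* Rasters travel as 8-bit TIFF with an ESRI world file (`.tfw`, pixel sizes
  plus the center of the top-left pixel) and a `.prj` sidecar carrying the
  CRS tag verbatim; the package treats CRS strings as opaque and never
  reprojects. Vector layers travel as GeoJSON or ESRI Shapefile
  (point/polyline/polygon); shapefile attribute names are truncated to the
  format's 10-character limit with a returned renaming map.

## Annotations, tiling, augmentation

Boxes are 0-based half-open internally; PASCAL VOC's 1-based inclusive
`bndbox` is converted only at the XML boundary, so a VOC box
`(1,1,10,10)` is internal `(0,0,10,10)` and round-trips bit-stably.

Tiling cuts a non-overlapping grid of `tile_size` (default 416) px;
remainder tiles keep their native size — no resizing, so object scale is
preserved. A box is copied into every tile it intersects, clipped, and
dropped where the clipped area falls below `min_visibility` (default 0.25)
of the original — a standard detection-dataset choice; before that filter
the clipped copies account for the full original area, a property the test
suite checks.

Rotations are exact right-angle remaps; 90° is defined **clockwise**
(`(x, y) -> (H - 1 - y, x)`), a convention fixed by testing the coordinate
remap against a pixel-level mask-rotation oracle. Brightness/contrast is
`clip(round(alpha * v + beta), 0, 255)` applied uniformly to all channels
(per-channel variation is possible by composing calls). Augmentation is a
deterministic expansion — originals, then rotations, then colour variants —
so 1,000 tiles under a factor-3 configuration become exactly 3,000
annotated images, with ids suffixed and boxes transformed alongside.

## Detection

The detector is a *contract*: any function mapping a tile to scored boxes
sorted by descending score (ties by `(ymin, xmin)`) plugs into counting and
evaluation. The shipped reference implementation is classical and fully
deterministic: HSV thresholding (red hue window, saturation/value floors),
connected components, area and compactness filters, tight boxes, greedy
NMS. The score is `min(1, 4πA/P²)` with the perimeter counted as exposed
pixel edges — a bounded compactness index that is monotone with
"disk-likeness", documented as a stand-in rather than a probability. A
learned detector trained on real imagery can replace it without touching
any other stage. The counting threshold `score_floor` defaults to 0.5 and
counts are provably non-increasing in it.

## Evaluation

Matching is greedy and one-to-one: detections in descending score order
each claim their highest-IoU unmatched truth box, subject to
`IoU >= iou_min` (default 0.5, the community criterion; both deliberate
choices exposed as configuration). Greedy matching is the detection-benchmark
standard and deterministic, but it is not guaranteed optimal: interlocked
configurations exist where it scores one TP fewer than exhaustive maximum
matching, and the suite contains such a case asserting the
`tp >= optimal - 1` bound. On independently drawn random instances (500
per run, ≤ 6 boxes) it coincides with the brute-force optimum.

Per picture: `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, and
accuracy `A = TP/Nfp` with `Nfp` the manual fruit count. With zero
detections precision and F1 are reported missing, never silently 0. All
arithmetic is unrounded; presentation rounds half-up to 2 decimals
(matching how printed agronomy tables round), and table averages are taken
over unrounded values.

## Calibration: visible counts to totals

`linear_fit` is plain OLS with intercept, reporting `R² = 1 - SSres/SStot`
(equal to the squared Pearson correlation in this simple case, covering
both common readings), MAE and RMSE.

`fit_calibration` deserves its own paragraph, because the obvious choice is
wrong. The prediction task is reference-total from detected-count, which
suggests regressing `reference ~ detected`. But `detected` is the *noisy*
variable — binomial thinning plus per-tree visible-fraction scatter — so
OLS on it suffers classical errors-in-variables attenuation: under the
generator's own defaults the fitted slope lands near 1.1 when the true
reciprocal visible fraction is ≈ 2.79, a 60% bias no amount of data fixes.
The default method is therefore `"classical"` calibration: fit the forward
measurement model `detected ≈ v * reference` through the origin, weighted
by `1/reference²` (the error scale grows with tree size, making this the
mean-of-ratios estimator `v̂ = mean(detected/reference)`), then invert to
the prediction scale `slope = 1/v̂`. On synthetic data this recovers the
reciprocal expected visible fraction within a few percent at 200
calibration trees. `method = "inverse"` retains the plain OLS direction
for comparison with studies that used it. Predictions are rounded half-up
and clamped at zero — totals are counts.

## Yield maps

The per-tree layer is one point per tree with its count and a half-open
class bin `[e_k, e_{k+1})`; default edges `(0, 20, 30, 40, 60, 80, 120, ∞)`
keep a `[30, 40)` class, the bin used in published summaries of this kind.
"Between 30 and 40" is read half-open, with a `closed = TRUE` escape hatch.
The per-row layer sums counts per row; its geometry is the first-to-last
tree line buffered into a thin rectangle (a display choice — block polygons
would work equally; the buffered line was chosen as the least committal).
Row totals always equal the sum of their trees' counts, and binning
partitions: every count falls in exactly one class.

## Numerical and degenerate-input choices

* Half-up rounding everywhere presentation rounding occurs (base R rounds
  half-to-even, printed tables do not).
* Empty cases are defined, not accidental: 0 rows → empty layout; no
  visible fruit → empty truth; no detections → precision missing; circles
  missing the raster → warning plus empty mask, and an error naming the
  tree when a crop is requested there.
* Degenerate distributions are exact: `concentration = Inf` pins stratum
  fractions, a single-value count range is honoured (with explicit
  indexing to avoid R's scalar `sample()` trap).
* Per-tree crop failures during batch counting log the tree and report
  `NA`, never abort the batch.

## Problem sizes used by the test and acceptance suites

Statistical properties run at: 1,000 trees for distribution recovery (means
within 3% / 2 points), ~12,000 fruits for the visibility expectation
(within 2 points), 200 calibration trees for slope recovery (within 10%),
40 paired replicates for the held-out-MAE comparison of 20- vs 200-tree
calibrations, 500 random instances for the matching oracle, 200 for the
NMS and rotation oracles, and 3 x 4-tree clean scenes at 10 mm/px for
end-to-end detection. These sizes make every stochastic check a
comfortable-margin Monte-Carlo estimate while keeping the whole suite in
well under a minute of compute.

## Known inconsistencies and limitations

* The survey table shipped in `inst/extdata/canopy_survey_counts.csv`
  contains one tree whose printed stratum counts sum to 319, although the
  accompanying narrative gives the range as 175-308. The package
  recomputes from the printed counts and reports max 319; the narrative
  range check is therefore expected to disagree on the maximum.
* The reference detector is a geometric stand-in; its perfect scores on
  clean renders say nothing about learned-detector accuracy on real
  imagery.
* Greedy matching can under-count TP by one on adversarial box
  configurations (see above).
* No CRS reprojection, no rotated/sheared affines, no multiband (> 3)
  rasters, no photorealistic rendering, no neural-network training or
  inference.
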