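---
title: "Methods: plant masking, synthetic compositing, anchors, grid loss and detection scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plant masking, synthetic compositing, anchors, grid loss and detection scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weeddetect)
```

## Scope

`weeddetect` packages the computational machinery around a two-class
weed/crop detector for sugar beet fields infested with hedge bindweed
(*Convolvulus sepium*): vegetation-index plant segmentation, a
cut-and-paste synthetic training-image generator, anchor-box estimation,
a declarative two-scale detection architecture with shape inference, the
grid detection loss, and AP/mAP scoring. Numeric network training and
inference are deliberately out of scope: the architecture graph carries
everything an execution backend needs (layer kinds, filters, routes,
shapes), but no weights. All components are exercised on procedurally
generated imagery, so the package is fully testable without any field
data.

## Plant segmentation: excess green and Otsu

Each RGB pixel is chromaticity-normalized, `r = R/(R+G+B)` and likewise
for g and b, and scored with the excess-green index `ExG = 2g − r − b`.
Because the normalized channels sum to one, `ExG = 3g − 1` at every
non-black pixel, so values live in `[−1, 2]`: green vegetation scores
high, soil and gray matter near zero. Pure black pixels (channel sum
zero) are defined to have `ExG = 0`, which keeps hard shadows out of the
plant class without a division-by-zero special case.

The ExG map is binarized with Otsu's method. Numerical choices, since a
real-valued index has no canonical histogram:

* values are linearly rescaled to the 8-bit range and histogrammed into
  256 equal-width bins, matching the algorithm's classic formulation;
  thresholds on raw-float histograms could differ marginally;
* the split maximizing between-class variance is found by exhaustive
  scan; ties are broken toward the lowest split;
* the returned threshold is placed midway between the closest observed
  values on either side of the winning bin boundary, so the
  strictly-greater mask rule (`ExG > threshold`; ties are background)
  reproduces the optimal histogram partition exactly;
* constant inputs raise an error (a degenerate histogram has no valid
  split) rather than returning an arbitrary cut.

No morphological cleanup is applied by default. For source photographs
known to contain a single plant, `plant_mask(keep_largest = TRUE)`
retains the largest 4-connected component (via EBImage).

## Cut-and-paste compositing

A synthetic training image is one *base* source (kept whole, soil and
all) plus one *object* plant pasted in. Transforms are sampled uniformly
and independently from fixed grids:

| component | object grid | base grid |
|---|---|---|
| rotation | 0–345° in 15° steps (24 values) | 0° or 180° |
| zoom | 0.5–1.5× in 0.1 steps | 1.0–1.8× in 0.1 steps |
| shift | −100…95 px in 15 px steps, each axis | none |
| flip | none / horizontal / vertical | none / horizontal / vertical |

The shift grid is the literal arithmetic progression from −100 px with
a 15 px step capped at +100 px; an inclusive-endpoint grid with that
step does not exist. The base grids never shrink or shift, so the soil
background keeps covering the canvas. The flip component samples
`none` alongside the two axes, so an untouched orientation remains
possible.

Geometric order is fixed as rotate → zoom (both about the canvas
centre) → shift → flip. The warp is computed by inverse mapping on a
canvas of the original size: images are resampled bilinearly, masks by
nearest neighbour, and regions exposed by the transform are filled
black / `FALSE`. The identity transform is bit-exact, 180° rotation is
an exact involution, and flips are exact axis reversals — properties
the test suite relies on.

Pasting follows the boolean-mask rule: wherever the transformed object
mask is true, the base pixel is replaced. Afterwards a gamma drawn from
{0.5, 0.7, …, 1.5} adjusts the whole composite's brightness
(`out = round(255·(in/255)^γ)`), applied after the paste so both plants
share the same photometric shift. Labels are tight boxes around the
transformed base mask (the base's own plant, kept even if partially
occluded by the paste) and the transformed, canvas-clipped object mask.

If an object transform leaves less than `min_visible_frac` (default
0.25) of the object's pre-transform mask area on the canvas — large
shifts and small zooms can push a plant off the edge — the pair of
transforms is resampled, up to `max_retries` (default 20) times before
erroring. Note that the 0.25 default interacts with the zoom grid: a
0.5× zoom alone leaves about 25% of the original area, so such draws
sit at the boundary and survive only when little else is clipped.

A dataset run enumerates every (crop base, weed object) pair once,
every ordered (weed, weed) pair including self-pairs, and a seeded
uniform subsample without replacement of the ordered (crop, crop) grid.
With 51 crop and 26 weed sources and 269 crop–crop pairs this is
1326 + 676 + 269 = 2271 composites. Every per-composite transform draw
derives from the single run seed, so identical inputs give bit-identical
outputs.

## Anchor estimation

Prior anchor sizes come from k-means on the training boxes' (w, h)
pairs. The default distance is `1 − IoU` of co-centred boxes — the
clustering criterion YOLO-family detectors use, scale-invariant where
Euclidean distance on pixel sizes is not; squared Euclidean remains
available. Initialization is k-means++-style seeding under a caller
seed, with `nstart` (default 5) independent restarts keeping the lowest
objective. Centroids update as per-cluster means; since the mean is
optimal for squared Euclidean but only a heuristic under `1 − IoU`, a
step that would raise the partition objective is rejected and the best
earlier state kept, making descent monotone and the reported centroids
always the means of their clusters. Empty clusters are re-seeded from
the point farthest from its centroid. Anchors are reported
area-ascending; for six anchors the three largest go to the coarse
(input/32) grid and the three smallest to the fine (input/16) grid, the
standard assignment for two-scale grid detectors. Because clustered
pixel sizes depend on the labelling resolution, the tools take an
explicit reference resolution rather than guessing one.

## The two-scale architecture graph

`build_graph()` emits an ordered layer table: five
convolution-and-max-pooling blocks whose 3×3 convolutions start at 16
filters and double per block (16→256), five stride-2 pools
(downsampling ×32), a 512/256/512 head to the coarse detection layer, a
route from the 256-filter bottleneck through a 128-filter 1×1
convolution and a 2× upsample, concatenation with the last encoder
block's convolution output, and two fusion convolutions to the fine
detection layer. Head channel depth is always
`anchors_per_scale · (5 + num_classes)` — 21 for the two-class,
three-anchor configuration. At 608×608 input, shape inference yields
19×19×256 at the encoder end and 19×19×21 / 38×38×21 detection
tensors.

Design points that were genuinely open: kernel sizes of head
convolutions beyond the stated filter counts follow the tiny-YOLOv3
convention (3×3 with 1×1 bottlenecks); the fusion pair is fixed at a
128-filter 3×3 followed by the head-depth 1×1; and the mid-head route
is resolved by position in the emitted layer list (0-based index 11,
recorded in the graph's `notes`). Layer indexing is 0-based. The graph
is declarative: `infer_shapes()`, `downsample_factor()` and
`parameter_count()` verify its arithmetic without executing it.

## Grid loss

Ground truth is encoded per scale onto an `S×S×B×(5+C)` tensor. A box
belongs to the cell containing its centre (half-open cells; a centre
exactly on a boundary goes to the higher-index cell) and to the anchor
with the highest co-centred IoU. The loss is the printed three-part sum
of squares with `α_coord = 5` and `α_noobj = 0.5`:

* **L1** — centre offsets and the square roots of width/height over
  responsible slots, weighted `α_coord`. Sizes are normalized to the
  image so the roots are defined on `[0, 1]`.
* **L2** — squared confidence error on responsible slots plus
  `α_noobj` times the same over background slots.
* **L3** — squared class-score error, summed per occupied *cell*. The
  cell-level object indicator is ambiguous when several responsible
  anchors share a cell; the term is then evaluated once, at the
  responsible slot with the largest target box. With at most one object
  per cell (the overwhelmingly common case) this reduces to the plain
  reading.

The loss operates on decoded values (offsets, fractions), not logits;
classification uses sum-of-squares rather than cross-entropy, following
the printed equations. Two boxes claiming the same (cell, anchor) slot
keep the larger, with a warning.

## Detection scoring

Detections pooled over the test images are sorted by descending
confidence (ties keep input order), greedily matched within image and
class to the unmatched ground truth of highest IoU, and flagged TP at
`IoU ≥ 0.5` — the conventional inclusive rule; a strict `>` variant is
available since "exceeds" could be read either way, and the two differ
only on exact-0.5 ties. AP is the left Riemann sum `Σ P(k)·Δrecall(k)`
down the confidence ordering — no 11-point or interpolated variants —
and mAP is the unweighted mean over classes. Per-image indexing of the
summation would not yield the area under a pooled PR curve, so the sum
runs over detections.

## The procedural field fixture

`generate_field_fixture()` stands in for unavailable field photographs:
a brown soil background (mean RGB 120/92/64) textured with
low-frequency luminance noise (±20 on an 8×8 coarse grid, bilinearly
upscaled) plus fine per-pixel jitter; class 0 plants as single large
rotated green ellipses (semi-major axis 10–16% of the short side, like
a young beet rosette seen from above); class 1 plants as clusters of
3–5 small green lobes (radius 2.2–3.5%), echoing bindweed's scattered
leaflets; plant colour centred on RGB 62/150/58 with ±12 jitter. Soil
chromaticity stays near `g = 1/3` (ExG ≈ 0) while plants sit near
`ExG ≈ 0.67`, so the index separates them by a wide margin. Masks are
analytic (ellipse/disk inequalities), mutually disjoint by construction,
and boxes are tight. Everything derives from one seed, so scenes are
bit-identical across runs.

What the fixture deliberately does **not** emulate: occlusion between
plants, specular highlights and cast shadows, leaf venation and texture,
growth-stage variation, and the colour ambiguity of young weeds against
young crop. Tests passing on fixtures therefore demonstrate the
*correctness of the machinery* — masking recovers known shapes,
composites conserve pixels, a perfect detector scores mAP 1 — not field
accuracy of any trained model.

## Problem sizes and determinism

The test suite runs on 64–160 px scenes, datasets of about a dozen
composites, clustering problems of tens of boxes, and grids with
`S ≤ 3` for the loss oracles — sizes at which every oracle (exhaustive
Otsu splits, exhaustive k-means partitions at n = 9, scalar-loop loss,
dense PR-curve integration) is exact and fast; the full suite completes
in well under a minute. The ±100 px shift grid is large relative to
such canvases, so dataset tests raise the transform retry budget to
100; at photographic scale the default 20 suffices. All randomness
flows through explicit seeds: samplers draw from R's stream, and every
pipeline entry point (`compose_pair`, `generate_dataset`,
`kmeans_anchors`, `generate_field_fixture`) takes a seed and restores
the caller's RNG state afterwards.

## Known limitations

* The architecture graph is declarative; there is no forward pass, so
  claims about inference speed or trained accuracy are outside what
  this package can verify.
* Otsu on rescaled 8-bit histograms can differ marginally from
  raw-float conventions in other toolkits; within an empty histogram
  gap the threshold position is conventional (the induced partition is
  what is well-defined).
* `1 − IoU` k-means with mean updates is a heuristic; the descent
  guard guarantees monotonicity, not global optimality — hence the
  multi-start default.
* The compositor places objects only via the shift grid (original
  position + sampled shift); it does not harmonize photometry beyond
  gamma, synthesize shadows, or build composites with more than two
  plants.
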