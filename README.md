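# weeddetect

Building blocks for image-based weed/crop detection in row-crop fields,
aimed at the sugar-beet vs hedge-bindweed (*Convolvulus sepium*)
setting: plants must be found and classed in top-down field photographs
so that a site-specific sprayer can act on weeds only. Training such a
detector is data-hungry, and labelled field images are scarce — hence a
pipeline that manufactures labelled training images by cutting masked
plants out of a few source photographs and pasting them onto
transformed backgrounds.

The package implements, in plain R:

* **Plant masking** — chromaticity normalization `r = R/(R+G+B)` (and
  likewise g, b), the excess-green index `ExG = 2g − r − b = 3g − 1`,
  and Otsu's between-class-variance threshold on a 256-bin histogram,
  giving a plant/soil binary mask.
* **Cut-and-paste compositing** — seeded geometric transforms on fixed
  grids (rotation 0–345° step 15°, zoom 0.5–1.5× step 0.1, shift
  ±100 px step 15 px, flips; restricted grids for base images),
  boolean-mask pasting, whole-composite gamma correction
  (γ ∈ {0.5, 0.7, …, 1.5}), automatic darknet-style labels, and a
  dataset scheduler (all crop×weed pairs, all weed×weed pairs, a
  seeded crop×crop subsample).
* **Anchor estimation** — k-means on box (w, h) with the
  `1 − IoU(co-centred)` distance (squared Euclidean optional),
  k-means++ seeding, monotone descent, and the fine/coarse scale split
  by area.
* **Architecture graph** — a declarative two-scale tiny-YOLO-style
  detector (five conv+pool blocks 16→256 filters, ×32 downsampling, a
  bottleneck route with 2× upsample and concatenation, two fusion
  convolutions) with shape inference, downsample-factor and
  parameter-count checks. Heads carry `B·(5 + C)` channels.
* **Grid loss** — target encoding (cell of the box centre, best-IoU
  anchor) and the three-part sum-of-squares loss
  `L = L1 + L2 + L3` with `α_coord = 5`, `α_noobj = 0.5`:
  coordinates (with √w, √h terms), objectness, and per-cell
  classification.
* **Detection scoring** — corner-box IoU, greedy confidence-ordered
  matching at IoU 0.5, precision–recall curves, AP by left Riemann
  summation, and mAP.
* **Procedural fixtures** — a seeded generator of plant-on-soil scenes
  (brown textured background, ellipse "crop" and multi-lobe "weed"
  blobs) with exact masks and boxes, so everything above is testable
  without any field data.

## Worked example

```r
library(weeddetect)

# a seeded synthetic field scene: 1 crop, 2 weeds on textured soil
scene <- generate_field_fixture(seed = 42, hw = c(160, 160),
                                n_beet = 1, n_weed = 2)
mask <- plant_mask(scene$image)    # ExG + Otsu
sum(mask)
#> plant pixels: 1119 of 25600

# score a detector that nails the crop but misplaces one weed box
gt <- cbind(image_id = "scene42", labels_to_boxes(scene$labels, c(160, 160)))
dets <- cbind(gt, confidence = c(0.95, 0.9, 0.8))
dets$xmin[3] <- dets$xmin[3] + 40; dets$xmax[3] <- dets$xmax[3] + 40
res <- evaluate_detections(dets, gt)
res$per_class
#>   class_id  ap n_gt n_det
#> 1        0 1.0    1     1
#> 2        1 0.5    2     2
res$map
#> mAP 0.750
```

The crop class (one detection, perfectly placed) scores AP 1; the weed
class keeps one of two boxes, so its precision–recall area is 0.5, and
the mAP is the class mean, 0.75.

The architecture arithmetic is equally direct:

```r
g <- build_graph(num_classes = 2, anchors_per_scale = 3)
infer_shapes(g, c(608, 608))[c(15, 22), ]
#>    index   kind height width channels
#> 15    14 detect     19    19       21
#> 22    21 detect     38    38       21
```

Both detection heads emit `3 · (5 + 2) = 21` channels, on the 19×19
(input/32) and 38×38 (input/16) grids.

A command-line front end wrapping these functions ships in
`inst/cli/weeddetect` (subcommands `mask`, `synth`, `anchors`,
`shapes`, `loss-check`, `eval`, `fixture`).

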