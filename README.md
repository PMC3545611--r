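# peachlut

Color look-up-table detection and tracking of red peaches in orchard
images, for embedded-style real-time fruit harvesting pipelines.

## The problem

An autonomous harvesting arm needs to find a red peach in an RGB image
and keep updating its position as the gripper approaches — at frame
rate, on hardware with kilobytes of memory, not gigabytes. Per-pixel
color classification (thresholds, nearest-color-model distances) is
either too crude or too slow for that budget. The classic answer is a
**three-dimensional segmentation look-up table (LUT)**: classify every
possible color once, offline, and store one fruit/not-fruit bit per
color. At run time, segmentation is a single memory read per pixel.

The index space is the 16-bit **RGB565** code — 5 bits red, 6 bits
green, 5 bits blue, the native format of small CMOS cameras — so the
full table is a 32 × 64 × 32 bit grid: 8 KB bit-packed, or 64 KB as one
byte per bin for faster addressing. (The equivalent 24-bit-color table
would be 2 MB.) For a pixel with code *c*, the segmentation is simply
*s = LUT(c)*; in the bit-packed layout the high 13 bits of *c* select a
byte and the low 3 bits a bit within it.

Two training routes build the table from labeled fruit pixels:

* **Linear color models (LCM).** Each object class — four peach skin
  variants (bright, dark, yellowish, brownish) plus foliage, wood, soil,
  sky — is a **line segment in RGB space** with a distance tolerance:
  the segment is the first principal axis of the class's pixel cloud,
  so it captures how the object's color slides along its illumination
  locus and can *extrapolate* to lighting never seen in training.
  A pixel belongs to the nearest segment (within its radius). The
  11-class set is classified once over all 65,536 bin representatives
  to fill the LUT; segmenting through the LUT is then *exactly*
  equivalent to the (far slower) per-pixel classification.
* **3D color histogram.** Count every labeled fruit pixel into its
  RGB565 bin; a bin with count strictly above a threshold (zero by
  default) becomes 1. Training recall is 100% by construction, but the
  histogram cannot extrapolate to colors it never saw.

Around the table, the package implements the rest of the detection
stack: camera acquisition simulation on a 640 × 480 sensor (**normal**
mode: full field of view, 2×-subsampled to 320 × 240; **zoom** mode: a
full-resolution 320 × 240 window re-centered on a detected fruit),
threshold-rule baselines, centroid computation and the normal→zoom
tracking state machine, plus an evaluation protocol (area relative
error and noisy-pixel fraction, stratified by illumination and
occlusion bins) driven by a seeded synthetic-orchard generator with
exact per-fruit occlusion ground truth.

## Worked example

```r
library(peachlut)

ms  <- default_model_set()        # 11 linear color models, 4 fruit classes
lut <- build_lcm_lut(ms)
lut
#> <segmentation_lut> 32 x 64 x 32 bins, layout: bitpacked (8192 bytes), provenance: lcm
#>   popcount: 4415 / 65536 bins set

scene <- generate_scene(scene_params(n_fruit = 2, seed = 7))
scene
#> <orchard_scene> scene-7: 2 fruit, bright illumination, occlusion none
#>   occlusion ratios: 0.00, 0.00

step <- track_step(scene$frame, lut)          # wide view, subsampled
step$centroid
#> <centroid> (128.00, 168.50), support 1514
step$next_state
#> $mode: "zoom";  $window_origin: 136 177

step2 <- track_step(scene$frame, lut, step$next_state)  # zoomed re-detection
step2$centroid
#> <centroid> (119.99, 160.06), support 6077
```

The first step detects the largest fruit in the wide view: 1,514 fruit
pixels with centroid at row 128.0, column 168.5 (0-based QVGA
coordinates). That detection re-centers a full-resolution zoom window on
the fruit, so the second step sees it at 4× the pixel count
(support 6,077) with the centroid now near the window center
(120, 160) — the increased-accuracy close-up a gripper controller would
consume. `lut_popcount`, `convert_layout`, `save_lut`/`load_lut` manage
the table itself; `histogram_to_lut(fit_histogram(...))` is the
histogram route to the same object.

A command-line surface over the same functions lives in
`inst/cli/peachlut.R` (`simulate`, `build-lut`, `segment`, `track`,
`evaluate`).

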