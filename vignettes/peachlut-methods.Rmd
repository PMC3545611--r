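---
title: "LUT-based red peach detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LUT-based red peach detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peachlut)
```

## The segmentation model

Everything in this package revolves around one data structure: a binary
table over the 32 × 64 × 32 grid of RGB565 color bins. A pixel's 16-bit
code indexes the table; the stored bit *is* the segmentation. The table
exists in two physical layouts with identical logical content — one byte
per bin (64 KB, fastest addressing) and bit-packed (8 KB, eight bins per
byte, byte = `code >> 3`, bit = `code & 7`, LSB-first) — and three
provenances: tabulated linear color models, a thresholded 3D histogram,
or an explicit classifier.

**Quantization is by truncation** (`r >> 3`, `g >> 2`, `b >> 3`), the
way a camera discards low-order bits when it emits RGB565, not by
rounding. This matters because the histogram route counts *quantized*
training pixels: with truncation on both sides, the bin grid seen in
training and at inference is identical, which is what makes
training-set recall exactly 100% at threshold zero.

**Linear color models.** A class is a segment $[p_0, p_1]$ in RGB space
plus a radius $r$. Fitting takes the first principal axis of the
training cloud through its mean (via SVD of the centered cloud);
endpoints are the projections of the extreme pixels onto that axis,
clipped to the $[0,255]^3$ gamut; the radius is the maximum
perpendicular training distance, floored at 1 RGB unit so a perfectly
collinear cloud still accepts its own quantized pixels. Classification
assigns the nearest segment (Euclidean, point-to-closed-segment with
endpoint clamping); ties break to the lowest model index. A pixel
farther than the winner's radius is labeled `"unmodeled"` — rejection is
a package decision and can be disabled (`reject = FALSE`), since
nearest-class-always assignment is an equally defensible reading of the
approach. The distance is unweighted: no channel weighting scheme is
assumed.

**Tabulating models into a LUT** requires one RGB point per bin. We use
the bit-replicated expansion (`r5 << 3 | r5 >> 2`, etc.), the
conventional 565→888 mapping; any fixed in-bin representative would do,
but this one makes `encode(expand(code)) == code` an exact identity,
which the tests exploit. With that choice, segmenting an image through
the LCM-LUT is *pixel-identical* to classifying the quantized image's
representatives directly — an equivalence asserted exhaustively over all
65,536 codes in the test suite.

**Histogram route.** Counts are kept per RGB565 bin; the LUT marks bins
with value strictly above the threshold. At the default threshold of
zero, raw counts and probabilities (counts/total) select the same bins,
so no normalization is needed; a `mode = "probability"` flag exists for
nonzero thresholds where the count scale would be arbitrary. The
threshold is strict (`>`), so `threshold = max(count)` yields an empty
table — a boundary the tests pin down.

## Acquisition and tracking

The simulated sensor is a 640 × 480 matrix. *Normal* mode delivers
320 × 240 by taking every second row and column at phase 0 (even
indices, 0-based); *zoom* mode crops a full-resolution 320 × 240 window
whose origin must keep the window inside the sensor — out-of-bounds
requests are errors, never silently clamped, because a clamped window
would silently change what the controller is looking at. All
coordinates are (row, col), 0-based, top-left origin; the convention is
stated once and used everywhere.

The tracking step is a two-state machine: a detection in normal mode
re-centers a zoom window on the centroid (sensor coordinates = 2× QVGA
coordinates, then clamped so the window fits); an empty zoom
segmentation falls back to normal mode. Single-target tracking is the
default — the centroid is computed on the largest connected component
(8-connectivity by default, ties broken by earliest row-major pixel) —
with the global-centroid variant available, since a gripper approaches
one selected fruit at a time.

## Evaluation metrics

No standard formula exists for "area error" and "noisy pixels" in this
setting, so the package fixes:

* area relative error = $100\,|A_{pred} - A_{gt}| / A_{gt}$ (absolute,
  per image);
* noise fraction = $100\,|pred \setminus gt| / A_{gt}$.

Both denominators are configurable (`denom = "frame"` normalizes by the
image size instead); the ground-truth-area default makes the two
metrics comparable across fruit sizes. Aggregation over a stratum is
the unweighted per-scene mean; empty strata are reported as missing,
never zero. The evaluation ground truth defaults to the **full**
pre-occlusion fruit extent (the visible-only masks are also stored):
with full-extent truth, an occluded fruit's area error grows with its
occlusion ratio, which is the behavior of interest when judging how
occlusion degrades detection.

## What the synthetic orchard emulates — and what it does not

No public labeled orchard imagery accompanies this problem, so the
generator is a first-class module with exact ground truth. Each scene
is a 640 × 480 frame containing:

* a blocky background sampled from seven color loci (bright/dark
  foliage, grass, branch, trunk, soil, sky) on a 16-pixel cell grid;
* ellipsoidal peaches (default 3 per scene, semi-major axis 26–55 px,
  aspect 0.78–1.05) with radial shading along one of four skin-variant
  color loci — bright at the center, darker at the rim — so fruit pixels
  genuinely lie along a line in RGB space, the structure the linear
  color models assume;
* a global multiplicative illumination gain: `bright` = 1.0,
  `low` = 0.65 (a dim-but-usable overcast level; colors scale toward
  the origin, which is what a gain change does to a linear camera);
* per-pixel Gaussian channel jitter, default sd 4 (8-bit units), a mild
  sensor-noise stand-in;
* opaque leaf-shaped elliptical occluders drawn over each fruit until
  its occlusion ratio — computed *exactly* from the masks, never
  estimated — lands in the requested bin (<33%, 33–66%, 66–99%), with
  bounded rejection-resampling and inner target ranges kept clear of
  the bin edges. Occluders aimed at one fruit avoid covering others so
  each ratio stays independently controlled.

One batch seed drives per-scene derived seeds, so every scene is
independently reproducible and regeneration is bit-identical; the
generator saves and restores the caller's RNG state.

The palette values are this package's defaults, chosen to look like an
orchard under daylight; they are not measurements. The bundled 11-class
model set was fitted to samples drawn from these loci under both gains
and frozen as a JSON fixture (filename marked `synthetic`).

Passing tests on this imagery therefore show that the *machinery* is
correct — layouts agree, the LCM-LUT equals direct classification,
recall is exact, error grows monotonically with occlusion — not that
real orchard percentages are reproduced. Real imagery has texture,
specular highlights, mixed pixels at fruit boundaries, shadows that are
not a global gain, and color casts the generator does not model; its
clean class palettes also make the no-occlusion, matched-illumination
condition easier than reality. One realistic confusion the generator
*does* reproduce: dim-light fruit colors overlap bright-light wood and
soil colors, so LUTs trained across both illumination conditions pick
up cross-illumination false positives, and the histogram route —
which cannot extrapolate color/illumination relationships — suffers
more from this than the linear-model route.

## Problem sizes and numerical choices

The held-out recovery check trains a histogram LUT on 10 scenes and
evaluates 20 no-occlusion scenes plus 8 scenes per occlusion bin;
`scripts/acceptance.R` uses the same sizes with training split across
both illumination conditions (5 + 5). These sizes give stable stratum
means (standard errors well below the effect sizes of interest) while
keeping a full run in tens of seconds on one CPU. Layout equivalence is
checked over 100 random LUT/image pairs; geometric operations are
compared against brute-force oracles at 1e-6, integer operations
exactly.

Other fixed choices, stated once here: LUT bit order within a packed
byte is LSB-first (the natural shift/mask reading of the 13-bit
pointer / 3-bit offset split); serialization of tables and histograms
is raw little-endian payloads with JSON sidecars, because bit-exact
round trips matter more than a portable image container; threshold-rule
bounds live on the RGB565 bin scales (R, B in 0–31, G in 0–63) with
strict inequalities, and exclusive upper bounds may equal the channel
maximum + 1 to span a full range; degenerate inputs error loudly
(identical-pixel model fits, empty ground truth) except where the
pipeline needs a signal value (empty mask → a no-detection centroid
with `support = 0`).

## Known limitations

* Multi-class LUTs (one label per bin) are out of scope; the table is
  binary fruit/not-fruit.
* No shape cues: a red ball would segment like a peach. Shape-based
  detection is a natural extension, not implemented here.
* Tracking has no motion model; the state machine only re-centers and
  falls back.
* The generator's occlusion is opaque foliage only; translucent leaves
  and penumbra are not modeled.
* Timing claims (frame rates, per-algorithm milliseconds) belong to
  embedded hardware and are deliberately outside this package's scope.
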