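---
title: "Density-guided occlusion augmentation and counting evaluation for wheat ears"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-guided occlusion augmentation and counting evaluation for wheat ears}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earcount)
```

## The problem

Counting wheat ears in field images is a standard proxy for yield
estimation. Detection-based counters (one bounding box per ear, count the
boxes) fail most often where ears occlude one another or are hidden behind
leaves and stems — and in a dense canopy that is almost everywhere. Two
levers against this failure mode live outside the detector itself and are
what this package implements:

1. **Random-Cutout**, an augmentation that erases rectangles from training
   images so the model learns to recognise partially hidden ears. Unlike
   the classical Cutout (fixed-size squares, uniform positions) and Random
   Erasing (noise rectangles, uniform positions), both of which are also
   provided as baselines, Random-Cutout ties the *position* of the erasure
   to local ear density and its *size* to the ears actually present in the
   image.
2. **CBAM**, a convolutional block attention module, provided here as an
   exact numeric reference (no training, weights are inputs) so that a
   detector-side implementation can be validated against it.

Around these sit the plumbing a counting study needs: annotation I/O in
three dialects, detection post-processing (confidence filtering and NMS),
the counting metrics, and a synthetic scene generator so every component is
testable without downloading a dataset.

## The augmentation model

For an image with ground-truth boxes, the per-pixel placement weight is

$$I_i = 0.001 + 0.003\, n_i,$$

where $n_i$ counts the boxes whose half-open extent contains pixel $i$.
The floor of 0.001 keeps every pixel reachable: occlusion by leaves and
stems also happens away from ear clusters, so the augmentation must not
become impossible in sparse regions. The increment 0.003 per overlapping
ear makes a pixel inside one ear 4 times more likely than background, and
density compounds — pixels under $k$ stacked ears carry $0.001 + 0.003k$.
We treat the warm/cold rendering of this map as visualisation only; no
smoothing is applied, because the sampling distribution, not its look, is
what the method defines.

Erasure parameters, per image with $N_{total}$ ears:

* **count** $N = \max(1, \lfloor N_{total}/4 \rfloor)$. The divisor 4 is
  the default `n_rect_divisor` of `cutout_config()`. The floor-with-minimum
  is our reading of the bare ratio: an augmentation that silently does
  nothing on images with fewer than four ears would contradict the premise
  that sparse regions get occluded too, so one rectangle is always placed
  when at least one ear exists.
* **centres** are drawn from the normalised map, without replacement.
  A two-stage scheme (large candidate pool, then subselection of $N$) is
  collapsed into direct weighted sampling — the selected centres follow the
  same distribution and one stage less needs configuring.
* **sizes**: height uniform on $[H_{min}/4,\,H_{max}/4]$ and width uniform
  on $[W_{min}/4,\,W_{max}/4]$, where the bounds are the extreme box
  heights/widths *of that image*. Scaling with the image's own ears matters
  because ear pixel sizes vary several-fold with the camera's field of
  view; a fixed erasure size either vanishes on close-ups or swallows whole
  regions on wide shots. "Length" is mapped to box height and "width" to
  box width; with axis-aligned boxes these are the only size summaries
  available.
* **fill** is white (channel maximum) by default; `random_noise` and
  per-channel `mean` fills are options.

Boxes are returned unchanged: the erased rectangles simulate occlusion, and
the labels must keep supervising the occluded ears — that is the entire
point of the method.

## CBAM as a numeric reference

Channel attention: $M_c = \sigma(\mathrm{MLP}(\mathrm{AvgPool}(F)) +
\mathrm{MLP}(\mathrm{MaxPool}(F)))$ with one shared bottleneck MLP
$W_1\,\mathrm{ReLU}(W_0\,x)$ and no biases. Spatial attention:
$M_s = \sigma(f^{7\times7}([\mathrm{AvgPool}(F);\mathrm{MaxPool}(F)]))$
with pooling along the channel axis. Refinement is two multiplicative
gatings, $F' = M_c \otimes F$ then $F'' = M_s(F') \otimes F'$.

Decisions a reader should know about:

* **Weight shapes.** Writing $W_0 \in \mathbb{R}^{C/r \times C}$ together
  with $W_1 \in \mathbb{R}^{C/r \times C/r}$ cannot compose to an output of
  length $C$, so the module could not gate $F$ channel-wise. The shapes
  used here are $W_0 \in \mathbb{R}^{C/r \times C}$,
  $W_1 \in \mathbb{R}^{C \times C/r}$ — the standard CBAM convention and
  the only one under which the refinement type-checks.
* **Reduction ratio.** `r` is carried explicitly by the weight object; 16
  is the conventional default in the attention literature, and
  `random_cbam_weights()` uses it unless told otherwise.
* **Padding.** The 7×7 convolution uses same-size zero padding, since
  $M_s$ must be multiplicable with the feature map.
* **Pooling reading.** Mentions of larger pool filters (7×7, 15×15) for
  the spatial descriptors are read as describing the convolution's
  receptive field; only channel-direction pooling is applied before the
  convolution.
* **Axis order** is `(W, H, C)` at the interface, matching the
  $\mathbb{R}^{W\times H\times C}$ convention for feature maps; image
  arrays elsewhere in the package are `[row, col, channel]`.

The implementation is deliberately loop-light but not clever; its contract
is agreement within $10^{-10}$ with naive scalar-loop evaluation, which the
test suite checks across shapes up to 8×8×8. Note one numerical caveat: for
logits beyond roughly ±37 the sigmoid saturates to exactly 0 or 1 in double
precision, so the "strictly inside (0, 1)" property is meaningful only for
moderate weight and feature magnitudes.

## Post-processing and metrics

Confidence filtering keeps boxes *strictly above* the threshold (default
0.5 — "higher than" is read literally, so a box at exactly 0.5 is
rejected). NMS is the greedy descending-confidence scheme; its IoU
threshold is nowhere fixed by the method description, so 0.5 is a
configurable default. Confidence ties break toward the larger box, then
input order — determinism is a requirement for testing, not an afterthought.

Counting accuracy and false detection rate are

$$P = N_{cor}/N_{real}, \qquad O = N_{err}/N_{num},$$

with $N_{cor}$ defined by greedy one-to-one matching in descending
confidence at IoU ≥ 0.5 (inclusive — deliberately distinct from NMS's
strict inequality; both conventions are stated at the interfaces). The
matching rule is our operationalisation of "detected correctly": the ratio
definitions presuppose a correct/incorrect partition but do not define one,
and greedy-by-confidence is the standard benchmark convention. Zero
denominators yield `NA` plus a defined-ness flag, never a silent 0.

With several images, `count_report()` pools counts before forming ratios by
default; per-image averaging (mean of per-image ratios) is available via
`average = "per_image"`, since summaries of the form "average ± SD" imply
per-run averaging and the choice can matter. The report records which mode
produced it.

`timing_report()` implements FPS $= 1/T$ with $T$ the mean per-image
wall-clock time of a caller-supplied callable. FPS is a hardware property
as much as a model property; the package reports it but no test asserts a
particular value.

## What the synthetic scenes do and do not emulate

`generate_scene()` renders ears as rotated anisotropic ellipses with
spikelet-like banding and grain noise on a plain or cluttered background,
with exact ground-truth boxes. The generator reproduces the properties the
downstream modules actually consume:

* dense, mutually overlapping boxes (`overlap_fraction` steers the realised
  fraction of ears intersecting another ear; placement alternates
  adaptively between overlap-seeking and rejection-sampled free placement);
* several-fold scale variation via the ear size ranges;
* edge-truncated ears (centres may fall near the border; boxes are clipped);
* cluttered, stem-streaked backgrounds.

It does **not** attempt photorealism, lighting or maturity variation.
Passing tests therefore certify the geometry and the algorithms —
probability maps, placement distributions, size laws, matching, metrics —
not detector performance on real canopy photographs.

Defaults (256×256 canvas, 30 ears, lengths 24–48 px, widths 8–16 px,
overlap 0.5, cluttered background) describe a moderately dense plot image
in which roughly half the ears touch another ear — occlusion present in
essentially every image, without degenerating into a single clump.

`generate_detections()` adds the three canonical detector failure modes at
known rates — binomial misses, uniform per-edge jitter, false positives at
ear-free spots — with confidences uniform on (0.5, 1], mirroring a 0.5
acceptance threshold. Known construction rates make the metrics
recoverable: with `miss_rate = 0.10` the pooled accuracy estimate must land
on 0.90 within binomial error, and the conservation identities
$N_{cor}+N_{err}=N_{num}$, $N_{cor}+\text{missed}=N_{real}$ hold in every
run. In evaluation studies we use `jitter = 1` px on ears at least 8 px
wide: realistic localisation noise that a worst-case IoU analysis shows
almost never pushes a true detection below the 0.5 matching threshold, so
the matching stage does not bias the recovered rates.

## Numerical choices

* **Coordinates** are 0-based, half-open, x = column, y = row, origin
  top-left (the COCO convention; the Pascal VOC dialect's 1-based inclusive
  corners are converted at the boundary). Half-openness keeps adjacent
  boxes from double-counting shared edges in the probability map.
* **Bit-exactness of the map.** Box-membership counts are accumulated as
  integers and the affine formula applied once, so `build_probability_map()`
  is bit-identical to evaluating $0.001 + 0.003\,n_i$ pixel by pixel.
* **Clipping** touches only coordinates that actually cross a bound, so
  already-valid boxes pass through bit-identically, and clipping twice
  equals clipping once.
* **Continuous boxes.** Scene boxes are the tight analytic bounding boxes
  of the rotated ellipses, kept as floats (annotation formats store floats
  anyway). A corollary used by the tests: scaling the canvas and both size
  ranges by a power of two scales every box *exactly*, because geometry is
  drawn before any pixel is rendered and every placement decision is
  scale-invariant.
* **Rounding floors.** Realised erase rectangles are at least 1 px per
  side; rectangle extents clip at borders rather than resample.
* **RNG discipline.** Every stochastic function takes a `seed` and runs
  under an isolated RNG scope: fixed seed means bit-identical output, and
  the caller's RNG state is never disturbed. Sub-draw order within the
  augmentation (centres, then heights, then widths) is part of the
  contract.
* **Placement feasibility.** Ear placement retries under a global budget of
  100 attempts per requested ear; an ear larger than the canvas or an
  exhausted budget raises a generation error rather than looping.

## Problem sizes in the test suite

The deep property checks run at: 1,000 random scenes (≤128×128, ≤40 boxes)
for probability-map exactness; 1,000 rendered scenes for the erasure laws;
20 scenes × 10,000 draws for the chi-square sampling check; all feature-map
shapes up to 8×8×8 × 50 weight draws for CBAM; 500 fifty-box instances for
NMS; and 500 scenes × 50 ears for metric recovery. These sizes give the
statistical checks standard errors a factor ≳3 below the asserted
tolerances while keeping a full run inside a few minutes on one CPU.
`scripts/acceptance.R` re-derives the same quantities at moderately reduced
sizes and writes them as JSON.

## Known limitations

* The greedy matcher can differ from a maximum-cardinality matching when
  detections are badly displaced relative to a dense truth layout; the
  tests compare the two on jittered scenes, where they coincide.
* The chi-square sampling check is itself a statistical test: at α = 0.01
  a perfectly exact sampler still fails one scene in a hundred, so the
  acceptance script reports the pass *rate* across scenes rather than a
  single worst-case p-value.
* VOC XML stores integer pixel corners; boxes are rounded on write in that
  dialect only.
* The CBAM reference is a specification object, not a performance kernel:
  it is vectorised enough for feature maps of a few hundred thousand
  elements, not for training-scale workloads.
* Inserting CBAM into a detector (for instance between a backbone's
  multi-scale outputs and a feature-fusion neck, which is where it earns
  its keep for occlusion) and any training concerns are out of scope; the
  module here validates such implementations numerically.
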