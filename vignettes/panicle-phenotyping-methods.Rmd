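---
title: "On-panicle grain phenotyping: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{On-panicle grain phenotyping: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PanicleScan)
```

## The problem

Grain number, size and shape on a rice panicle are central yield and quality
phenotypes, but conventional measurement requires threshing the panicle and
arranging the grains, which is slow, destructive, and sensitive to handling.
PanicleScan implements a scanning-based alternative: a flatbed scan of the
intact panicle is calibrated through its resolution (a 600 dpi scan resolves
`25.4 / 600 = 0.0423` mm per pixel), grains are located on the dark scanner
background, silhouettes hidden by neighbouring grains or the rachis are
completed, and fifteen panicle-level traits are computed from the per-grain
measurements.

The pipeline is a cascade: **detect** each grain and cut a region of
interest, **restore** occluded silhouettes inside each region, **measure**
each grain in physical units, **aggregate** to panicle traits, and
**evaluate** any stage against ground truth with the standard metric suite
(R^2, MAPE, RMSE, PSNR, SSIM, average precision).

## Synthetic scenes as the test bed

No public scan set accompanies the method at desk scale, so the package
carries a first-class scene generator whose ground truth is exact by
construction. Every downstream claim the test suite makes is a claim about
these scenes; what they do and do not share with real scans is therefore
spelled out here.

A grain is modelled as a rotated superellipse `|u/a|^n + |v/b|^n = 1` with
semi-axes `a = length/2`, `b = width/2`. The exponent interpolates between
an ellipse (`n = 2`) and a rounded rectangle; the default `n = 2.5` gives
mid-range circularity (about 0.5 at the 3:1 aspect ratio typical of rice),
matching the intermediate value implied by the published mean area,
perimeter and circularity of real grains. Grain lengths are drawn from a
normal distribution with mean 8.607 mm and standard deviation 0.589 mm,
truncated to the observed 5-11 mm range; widths from mean 2.770 mm, sd
0.248 mm, truncated to 2-4 mm; orientations uniformly. These are the
published population values of the varieties the method was validated on,
used here as the emulated population. Scenes hold 45-250 grains, the
documented range of grains per panicle, on a 1425 x 1700 px canvas at
150 dpi — the working input scale of the detector (a quarter of the
5700 x 6800 crop of the raw 7200 x 10200 scan at 600 dpi).

Rendering is anti-aliased (3 x 3 supersampling) and quantized to 8 bits;
the ground-truth mask is defined by at least 50 % pixel coverage. Placement
is by rejection sampling: later grains are drawn on top of earlier ones,
and a placement is rejected when it would push any grain's occlusion ratio
(1 − visible area / full area) over the configured ceiling. At a ceiling of
zero an extra one-pixel gap is enforced so that disjoint silhouettes can
never touch under labelling.

What the generator deliberately does **not** emulate: awns, per-variety
colour, chalkiness, shading gradients, the branching topology of the
rachis, and the heavy-tailed clutter of real scanner plates. Passing tests
on these scenes demonstrate the geometry and statistics of the pipeline,
not robustness to real-image nuisance factors.

For restoration training and evaluation the generator builds paired
occluded/clean 256 x 256 crops. The occluder is either a second grain from
the same population or a thin dark strip standing in for the rachis; its
position is found by bisection along an approach direction so that the
realised cover of the grain silhouette hits the requested ratio within
±0.03. The paired-sample invariant is strict: a ratio of zero yields
pixel-identical images.

## Measurement conventions

All measurement happens on the red channel, where grain-to-background
contrast is strongest on the dark plate; the channel is used unchanged
(no luminance mixing). Otsu's threshold is computed over all 255 possible
8-bit splits by maximizing between-class variance, ties resolved to the
smallest threshold, foreground strictly above the threshold. A constant
image raises a typed error rather than returning an arbitrary threshold.

The contour of the largest connected component is traced along pixel
edges ("crack" boundary, vertices at half-integer coordinates). Two
consequences are worth noting and are frozen in golden tests:

* the shoelace area of the traced polygon equals the pixel count of the
  component, so the projection area convention (pixel count times
  `mm_per_px^2`) and the contour are mutually consistent;
* a filled 10 x 10 px square measures perimeter 40 (its crack outline),
  not the 36 of a pixel-centre chain.

The raw crack path overestimates the length of smooth boundaries by up to
8 % (staircase effect), so the perimeter is the arc length of the
Douglas-Peucker simplification of the crack polygon at a 1 px tolerance.
This removes staircase excess while keeping true corners; digital disks
then approach circularity 1 from below as the radius grows, and the
rendered-grain perimeter recovers the analytic superellipse perimeter to
well under 2 %.

Grain length is the exact maximum pairwise distance between contour
vertices, computed on the convex hull (hulls here have a few hundred
vertices at most, so exhaustive pairing over hull vertices is exact and
fast; the suite cross-checks it against an all-points brute force). The
achieving pair defines the major axis. Grain width sweeps lines
perpendicular to that axis at 1 px steps — contour points are binned by
their projection along the axis, the chord in each bin is the range of the
perpendicular coordinate, and the width is the largest chord. Sub-pixel
sweep steps were considered and rejected: at the working scale one pixel is
0.042 mm, an order of magnitude below the population standard deviation of
grain width.

Derived quantities follow the published trait table: length/width ratio,
area/perimeter ratio (the table's direction, area over perimeter, which is
consistent with its printed mean 18.140 / 21.313 = 0.851), circularity
`4*pi*A/P^2`, and an equivalent ellipse recorded as the ellipse with the
measured length as major axis and the measured area (minor axis
`4A/(pi*L)`) — an interpretation, since no formula accompanies the name,
and therefore not part of the fifteen aggregated traits.

Aggregation produces the fifteen panicle traits: grain number, and
mean/SD pairs of length, width, projection area, perimeter,
area/perimeter ratio, circularity, and length/width ratio. The SD is the
sample SD (n − 1) by default — the convention is not fixed by the source
material, so it is a documented package choice with a population-SD
switch. A single grain reports SD 0. Thousand-grain statistics draw 1000
grains without replacement (with replacement, plus a warning, from smaller
pools) and histogram length, width and length/width ratio over fixed bin
edges.

## Detection

The desk-scale detector is classical and fully deterministic: Otsu
segmentation of the red channel, then a watershed of the Euclidean
distance transform to separate touching grains. Seeds are the regional
maxima of the distance map with maxima closer than 1 (inclusive) in
distance value merged — the quantization scale of the map. The rule was
chosen over a half-of-maximum seed threshold after that variant failed a
specific, reproducible case: a small grain fused to a large one
contributes no second seed above half of the joint maximum, while it does
retain its own regional maximum. With the regional-maxima rule, isolated
convex grains keep exactly one seed (zero-occlusion counts are exact over
seeded scene batteries), and counts on scenes at a 0.2 occlusion ceiling
stay within a few percent. Box scores are blob solidity (area over convex
hull area). Crossing, strongly collinear merges remain the main failure
mode, as they present no distance-map evidence of being two objects.

The trainable path is a compact two-stage detector with feature-pyramid
fusion, exposing the published working point as its configuration
defaults: 1425 x 1700 input, NMS threshold 0.74, 4000 proposals, depth-50
backbone choice, SGD at learning rate 0.02 with momentum 0.9 and weight
decay 1e-4, batch 1, 100 epochs. The backbone extracts features at strides
2/4/8, lateral 1 x 1 projections align channel widths, and the upsampled
deep map is added to the shallow one before a 3 x 3 fusion convolution —
the multi-scale fusion that matters for small, densely packed targets. A
proposal head predicts per-cell objectness and box deltas against square
anchors; a second stage re-scores pooled proposal features. Layers are
implemented over the package's own convolution kernels with hand-written
backward passes; training clips the global gradient norm (the published
learning rate is far above what a compact net tolerates raw). The package
ships no weights: the learned path's contract is smoke-scale —
overfit-one-batch loss decrease and non-empty predictions on the training
scene — not a trained detector.

## Restoration

The geometric baseline completes a silhouette whose occluder footprint is
known (in the pipeline, the footprint of neighbouring detections). The
visible silhouette is segmented outside the occluder, contour points
bordering the occluder are discarded as cut artifacts, a direct
least-squares ellipse fit (Fitzgibbon's constrained eigen formulation,
with the numerically robust conic-to-geometry conversion) is applied to
the remaining points, and the hidden region is filled where it falls
inside the fitted ellipse. By construction the restored silhouette
contains the visible one. The fit needs at least 30 % of the estimated
silhouette visible; below that the function fails with a typed error
rather than guessing. Because grains are near-elliptical, end- and
side-occlusions at a 0.3 ratio restore length and width to a few percent;
the baseline's own error floor comes from fitting an ellipse to a
superellipse.

The learned path mirrors the published architecture at reduced width: a
U-Net generator (stride-2 halving encoder, nearest-neighbour-doubling
decoder, skip concatenation at every level, sigmoid output) and a fused
discriminator in which a patch head (kernel-4 stack with strides
2, 2, 2, 1, 1 — a 30 x 30 score map with a 70 px receptive field at
256 px input) and a global head (trunk-feature average into a dense
sigmoid unit) consume the same condition/candidate pair. Configuration
defaults are the published working point: 256 x 256, batch 64, Adam at
2e-4, 500 epochs. Choices the source leaves open are exposed as
configuration with these defaults: L1 reconstruction weight 100 against
adversarial weight 1 (the convention of the image-translation family this
model extends), 1:1 global:patch fusion, and a patch grid that defaults to
the head's natural map size (an explicit `N` pools the map; `N = 1`
degenerates the patch head into a second global score). The occluder mask
is an input to the geometric baseline but never to the network, which must
infer occlusion from the image alone. Training is fully seeded and
deterministic on one CPU thread; divergence raises an error.

## Evaluation metrics

R^2, MAPE and RMSE follow their textbook forms (MAPE requires nonzero
truths and errors on zero). PSNR uses `MAX_I = 255` with the mean squared
error averaged over channels for RGB input; identical images return an
explicit `Inf` sentinel, a legal outcome rather than an error. SSIM is
computed from whole-image statistics — one global window, exactly as the
formula is printed — with the standard stabilizing constants
`c1 = (0.01 * 255)^2`, `c2 = (0.03 * 255)^2`; a windowed mode exists
behind a flag for comparability but is off by default, and global SSIM is
the quantity all package figures report. Average precision uses greedy
score-descending matching (ties to the earlier index) at a given IoU
threshold and all-points interpolation of the precision-recall curve; the
reporting thresholds are 0.50 / 0.75 / 0.95. Each of Otsu, NMS and AP is
tested against an independent brute-force oracle.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a single CPU: parameter
recovery over 500 rendered grains at 600 dpi; counting over 20 simulated
scenes each at zero occlusion (exact counts required) and at a 0.2
ceiling (count MAPE within 5 %); restoration ordering over 50 pairs at a
0.3 ratio (restoration must strictly reduce the error of all four of
length, width, perimeter, area, and raise mean SSIM and PSNR); smoke
training at 64 px and at most a few hundred steps. The acceptance script
re-derives the same quantities from scratch at moderately smaller sizes
(300 grains, 12 scenes per condition, 30 pairs).

Numerical conventions collected in one place: boxes are half-open
`[x0, x1) x [y0, y1)` in 0-based, y-down pixel coordinates, so area is a
product of differences; dpi is stored per image and mixed-resolution
batches are legal; dataset splitting shuffles under the given seed before
slicing, with floor-sized parts and the remainder assigned to the earliest
parts (160 at 2:1:1 gives 80/40/40, 2000 at 8:2 gives 1600/400); Otsu ties
take the smallest threshold; the NMS order is score-descending with
index tie-break; the watershed merge tolerance comparison is inclusive;
and every stochastic entry point takes an explicit seed and restores the
caller's RNG state.

## Known limitations

* The baseline restorer requires an occluder mask; on real scans that mask
  must come from neighbouring detections, so detection misses propagate
  into restoration.
* Ellipse completion cannot represent asymmetric grain tips; its error
  floor on strongly non-elliptical grains is a few percent.
* Crossing grain pairs with collinear overlap defeat distance-transform
  splitting; the learned detector path exists precisely because the
  classical baseline plateaus there.
* Synthetic scenes omit real-image nuisance factors (texture, awns,
  lighting); results on them bound geometry and statistics only.
* The learned stages are contracts with smoke-scale evidence, not trained
  models; no claim is made about their full-scale accuracy.
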