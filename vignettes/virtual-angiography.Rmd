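---
title: "Virtual angiography of ultrasound cine loops: methods and design"
author: "camangio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual angiography of ultrasound cine loops: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camangio)
```

## The model

A B-mode cine loop is an ordered stack of co-registered grayscale
frames $\mathbf{I} = \{I_1, \dots, I_T\}$, $I_t \in \mathbb{R}^{M
\times N}$. The central assumption is that the *background* of
successive frames is identical: tissue does not move between frames,
so any frame-to-frame intensity change at a pixel is attributable to
moving scatterers — in CAM imaging, flowing nucleated erythrocytes
whose motion decorrelates the speckle inside vessel lumens.

Under that assumption the absolute finite differences
$|\Delta I_t| = |I_{t+1} - I_t|$ carry blood-flow evidence, and their
mean

$$
I_{VA} \;=\; \frac{1}{T-1}\sum_{t=1}^{T-1} |\Delta I_t|
$$

is the *virtual angiogram*: exactly zero wherever the temporal trace is
constant, positive wherever speckle moves. The streaming form
$I_{VA,t} = ((t-1)\,I_{VA,t-1} + |\Delta I_t|)/t$, with $t$ counting
differences consumed, reproduces the batch mean and lets the map build
up while a clip is acquired. Both forms are implemented
(`angiogramBatch`, `angiogramOnlineUpdate`) and agree to $10^{-9}$ per
pixel; accumulation is always in double precision.

Useful identities follow directly and are enforced by tests: the
angiogram is nonnegative, invariant under adding a constant to every
frame, homogeneous of degree one under intensity scaling, and exactly
null for a static loop. It *does* depend on frame order — adjacent
differencing is not permutation-invariant — and no property test
pretends otherwise.

### What the angiogram is not

No frame registration is applied: the differencing model presumes
co-registered frames, and whole-embryo motion shows up as artifact, not
signal. Doppler-style velocimetry, windowed/sliding accumulation and
microbubble localization are out of scope.

## From angiogram to annotations

Annotation operates on a display rendering of the angiogram:
`enhanceForDisplay` clips at an upper percentile (default 99.5) and
rescales linearly to $[0,1]$. The percentile clip is a deliberate
choice — raw angiograms have heavy-tailed maxima from single flickering
pixels, and clipping them preserves usable contrast for the rest of the
image. The mapping is monotone below the clip and records the (lo, hi)
range used. An all-zero angiogram maps to an all-zero image rather than
dividing by zero.

### Interpolated boundaries and curves

Manual annotation reproduces clicked points exactly, so the
interpolants are *interpolating* cubic splines, not approximating
B-splines: periodic for closed CAM-vessel boundaries (parameterized by
point index, resampled uniformly, at least 8 output samples with knots
kept on the sample grid), natural for open microvessel curves (a
straight segment when only two points are given). Duplicate
consecutive points are collapsed with a warning.

### Active contour

`snakeSegment` evolves a closed contour initialized from the outer
contour of the largest connected component of a rough ROI mask. The
energy is the classical one: elasticity $\alpha$ on the first
derivative, rigidity $\beta$ on the second, and an external edge energy
equal to the negative gradient magnitude of the Gaussian-smoothed
($\sigma$) display image. Evolution uses the standard semi-implicit
scheme — the cyclic pentadiagonal internal-energy system is inverted
once, the image force is applied explicitly with bilinear sampling, and
per-step displacement is capped at 1 px.

Defaults (all exposed via `SnakeParams` and the YAML config) were
calibrated on a bright-disk phantom of radius 30 px with a radius-40
seed:

| parameter | default | meaning |
|---|---|---|
| `nPoints` | 200 | contour samples |
| `alpha` | 0.015 | tension (px$^{-2}$) |
| `beta` | 10 | bending stiffness (px$^{-4}$) |
| `sigma` | 2 px | Gaussian pre-smoothing |
| `gamma` | 0.001 | implicit-Euler step |
| `maxIter` | 2500 | iteration cap |
| `tol` | 0.1 px | mean per-iteration displacement for convergence |

Two numerical choices matter beyond the headline parameters. The edge
map is normalized to unit maximum, making the behavior invariant to
image contrast. The external force is then rescaled so its maximum
magnitude is $2\gamma$: strong enough to trap the contour at an edge
against the inward tension, weak enough that near-equilibrium steps
contract geometrically — with an unbounded force the contour dithers at
the step cap and the displacement test can never fire. With these
choices the disk phantom converges in a few tens of iterations with
mean radial error well under 1 px; on a gradient-free image the contour
shrinks under tension, and non-convergence at `maxIter` is reported as
a flag on the result, never as an exception. The snake runs on the
enhanced display image, not raw frames, matching the intended workflow
(angiography first, then annotation).

### Skeleton centerlines

Microvessel centerlines are the skeleton of a rough mask. Thinning is
the two-subfield Guo–Hall iteration: among the standard morphological
thinning schemes it preserves endpoints best (Zhang–Suen erodes bar
ends by roughly two extra pixels, enough to bias short-vessel lengths),
and it is parameter-free and deterministic. The skeleton is decomposed
into polylines broken at junctions, where a junction pixel has $\ge 3$
skeleton neighbors in 8-connectivity and *adjacent junction pixels
merge into one node* so a thick crossing is not double-counted.
Endpoint-to-junction spurs shorter than `prunePx` (default 5 px) are
removed, with re-thinning between rounds so a junction whose spur
vanished degrades gracefully to a through-path. Objects smaller than
2 px yield no curve.

Traced 8-connected chains zigzag on oblique vessels, inflating
Euclidean length by up to ~8% at 30°; each polyline is therefore
smoothed with an endpoint-anchored moving average (window 5), which
restores rotation-invariant lengths to within digitization error while
keeping consecutive samples within $\sqrt 2$ px.

## Quantification

Length is the Euclidean polyline length (diagonal steps count
$\sqrt 2$, avoiding the diagonal bias of pixel counting). Branch
points are the merged junction nodes of the skeleton. Local diameter
at a centerline point is twice the Euclidean distance transform of the
lumen mask at that point, averaged along each curve; without a mask,
diameters are reported as 0 with an explicit `hasMask = FALSE` flag.
Pixels are the primary unit; mm fields are mirrored only when a pixel
size is supplied. Measured lengths carry a constant $O(w)$ shortening
at tube ends (thinning cannot extend into the rounded cap), which is
why length checks use the $w + 2\,\mathrm{prunePx}$ band.

## The synthetic generator

`renderScene` emulates exactly the contrast mechanism the angiography
exploits, and nothing more: a background of mean 0.25 plus Rayleigh
speckle ($\sigma = 0.06$, blurred 1 px, clipped to $[0,1]$) that is
*frozen* across frames, and per-vessel point scatterers advected along
the centerline by `flow_px_per_frame`, wrapping at tube ends (a
conveyor, so density is stationary). Scatterers render as Gaussian
blobs (sd = half-width/2, amplitude 0.5) truncated at 3 sd — the
truncation is what makes "exactly zero outside the dilated tube" a
provable property rather than an approximation. Optional per-frame
Gaussian jitter (sd 0.01 in the noisy benchmarks) models electronic
noise. Three RNG substreams (background, scatterers, jitter) are
derived deterministically from the scene seed, so loops are
bit-reproducible and the background never depends on the frame count.

The scatterer density of the frozen benchmark scenes is 2 per
100 px²: sparse enough that overlapping blobs do not saturate the
clipped lumen (saturation freezes the temporal signal and destroys the
very contrast being modeled), dense enough that the 64-frame average
covers the tube.

Ground truth is analytic: the vessel mask contains pixels whose
distance to a centerline is *strictly* below the half-width. The
strict inequality makes a straight tube of half-width $w$ rasterize
$2w-1$ px wide with a distance-transform value of exactly $w$ on the
centerline, so the measured diameter $2\,\mathrm{EDT}$ recovers $2w$
for $w \in \{2,3,4,6\}$. Branch count is the number of positions where
at least three vessel-segment endpoints coincide, which is how the
benchmark trees are built.

What the simulator does **not** model: acoustic point-spread functions,
attenuation/TGC, out-of-plane motion, cardiac-cycle tissue motion, and
shadowing. Passing its tests therefore demonstrates the pipeline's
correctness under the stated contrast model, not robustness to every
artifact of live imaging — in particular, embryo motion violates the
static-background assumption and will contaminate real angiograms.

### Frozen benchmarks

All 256×256, 64 frames, half-width 4 px, flow 2 px/frame:
`single_tube` (straight, centerline length 200 px, 0 branch points),
`bifurcation` (a Y, 1 branch point), `tree3` (two-generation binary
tree, 3 branch points). Branch angles are ≥ 30° and tubes keep a
half-width margin from the frame edge.

## The automated pipeline

`cmdPipeline` chains simulate → angiogram → Otsu threshold → skeleton →
metrics → overlay. Otsu on the display image is the automatic stand-in
for the interactive annotation step. The thresholded mask is
regularized by a 3×3 closing and hole filling before skeletonization:
lumens are solid, so enclosed speckle dropouts are artifacts that would
otherwise punch loops (and spurious junction pairs) into the skeleton.
With defaults the pipeline recovers branch counts 0/1/3 exactly on the
three benchmarks across seeds, with Dice ≈ 0.8 against the true mask
under jitter.

## Conventions and I/O

Coordinates are 1-based (row, col) with row 1 at the top and pixel
centers at integers, uniformly across reader, simulator, annotations
and metrics — the convention native to R matrices, applied end to end
so a pixel drawn at (r, c) is read back at (r, c). All processing is
floating point on $[0,1]$; integer files are divided by the dtype
maximum (255 or 65535) on read — never by a per-file min/max, so
normalization is idempotent and intensities stay comparable across
files. Lossless multi-frame TIFF is the interchange format and round
trips bit-exactly at the quantized values (writing quantizes with
round-half-away-from-zero). AVI input is not supported; clips should
be converted to TIFF upstream. Annotations persist as JSON (points at
full float precision, masks run-length encoded); angiograms as 16-bit
TIFF with a JSON sidecar carrying `t_used`, the display range and the
scale factor.

## Problem sizes

The test-bench exercises the identities on 64×64 random loops (50
replicates, $T \le 32$), phantoms on 60–320 px grids, and the full
pipeline on the three 256×256×64 benchmarks — sizes chosen so the whole
suite runs in well under a minute per scene while every skeleton,
junction and contour remains large enough to be geometrically
nontrivial.

## Known limitations

* No motion compensation: embryo movement between frames produces
  angiogram artifacts by design of the differencing model.
* Skeleton lengths shorten by $O(w)$ at tube ends; branch counting
  depends on `prunePx` (documented, default 5 px).
* The snake handles one connected vessel per ROI; it will not split or
  merge contours.
* Diameters require a lumen mask; centerline-only annotations report 0.
* 3-D volumetry and perfusion indices are out of scope.
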