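---
title: "Quantifying structure and flow of retinal neovascularization in OCTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying structure and flow of retinal neovascularization in OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octanv)
```

## The measurement problem

In proliferative diabetic retinopathy, new vessels (NV) grow from the
retina through the internal limiting membrane (ILM) into the vitreous.
OCT angiography images such lesions twice over: a structural
(reflectivity) channel showing the vessel scaffold, and a flow
(decorrelation) channel showing only currently perfused lumen. Under
anti-VEGF treatment these two dissociate — flow collapses while the
scaffold largely persists as "ghost vessels" — and flow may return inside
the old scaffold when treatment stops. `octanv` implements a combined
measurement that keeps the two apart: the NV is delineated separately on
the en face structural image (NV-structure) and the en face angio image
(NV-angio), and flow density is measured inside each delineation.

## The en face measurement model

En face images are maximum-intensity projections of the
vitreoretinal-interface (VRI) slab, which starts at the ILM and extends
toward the vitreous as far as the NV reaches. In this package the axial
index z increases from the vitreous toward the deep retina, the slab is
the half-open range `top < z <= ilm` per pixel (the ILM voxel itself is
projected), and pixels with an empty slab project to 0.

Binarization of the angio image uses the Phansalkar auto-local threshold,
designed for low-contrast images: with the image normalized to [0, 1] by
its declared bit-depth maximum, a pixel with local window mean $m$ and
(population) standard deviation $s$ is foreground iff its value strictly
exceeds

$$t = m\,\bigl(1 + p\,e^{-q m} + k\,(s/r - 1)\bigr).$$

Defaults are the Fiji plugin defaults — circular window of radius 15 px,
$k = 0.25$, $r = 0.5$, $p = 2$, $q = 10$ — because the published method
names the plugin without parameters; the radius is the parameter that
matters most in practice and is exposed everywhere. Edge windows use
mirror padding (the method's reference implementation is silent on
boundaries; mirroring avoids darkening the border). Ties go to
background.

Flow density (FD) is the percentage of foreground pixels inside a mask.
Two deliberate fixed points of the pipeline:

* FD is **always** computed on the binarized **angio** image; the
  structural image only contributes its delineation. FD-angio masks by
  the NV-angio polygon, FD-structure by the NV-structure polygon, both
  from the *same* binarization.
* The full image is binarized first and the mask applied afterwards, so
  the local threshold at the lesion border sees the same neighbourhood
  regardless of the delineation.

Delineations are closed polygons in 0-based pixel coordinates with pixel
centers at integers. Rasterization uses the even–odd rule on pixel
centers; a center exactly on an edge counts as inside (a deterministic
tie-break — the alternative, dropping boundary pixels, makes thin
delineations vanish). Areas are mask pixel counts times the squared
lateral spacing, so they scale quadratically with spacing; the
longitudinal endpoints are relative changes and therefore unit-free.

## The B-scan measurement model

Device-exported B-scans are gray structural images with the flow signal
overlaid in red. Color-splitting and subtracting blue from red
(`max(R - B, 0)`, clamped at zero) removes achromatic gray exactly and
leaves the overlay, which is then binarized and masked like the en face
path. The NV delineation is bounded below by the ILM polyline and above
by the vitreous; a polygon dipping below the ILM is a geometry error.
Heights are single-column maxima (not averages) of the protrusion from
the ILM toward the vitreous — decreasing row index, row 0 at the top —
separately for the delineation (structure height) and for the topmost
binarized-flow pixel inside it (flow height), in µm via the axial
spacing. Flow height can never exceed structure height; an empty flow
mask yields height 0 with a warning rather than an error, since fully
regressed lesions are a real outcome. No axial spacing is asserted as a
device truth; both spacings are configuration inputs, and without them
B-scan areas are reported in px².

## Longitudinal endpoints

A series is one NV's visits (weeks strictly increasing, baseline at week
0) plus its injection weeks. The initial treatment block is the maximal
prefix of injections with successive gaps of at most 6 weeks (monthly
dosing); the posttreatment endpoint is the visit falling 5 ± 1 weeks
after the block's last injection — window `[4, 6]` weeks, closest to 5,
ties resolved toward the earlier visit — and the last endpoint is the
final visit. Area endpoints are signed relative changes
(`100 (v - b)/b`, negative = regression); FD endpoints are differences in
percentage points, reported decrease-positive. Missing B-scan values at a
visit are permitted; the en face columns are not. Series must keep one
pixel spacing throughout: the source data mixed scan patterns between
lesions, which limits between-lesion area comparability, and the pipeline
refuses to mix spacings *within* a series rather than silently rescale.

## Cohort statistics

Endpoints are summarized as median with range and mean with sample SD.
Confidence intervals use the normal multiplier,
$\mathrm{mean} \pm 1.96\,s/\sqrt{n}$: back-solving the reference
cohort's printed intervals (e.g. 51.9 ± 1.96·29.5/3 → 32.6 to 71.2)
identifies $z = 1.96$ exactly, not a Student t quantile. The test against
zero change is the Wilcoxon signed-rank with zero differences dropped,
average ranks for ties, tie-corrected variance
$n(n+1)(2n+1)/24 - \sum(t^3-t)/48$, and a two-sided normal p **without**
continuity correction — again the unique variant that reproduces the
printed p-values (0.26, 0.0077, 0.066, 0.015, 0.48). An exact
enumeration over all $2^n$ sign assignments is available
(`method = "exact"`) and is used in the tests to validate the rank
machinery, but is not the default. No multiple-testing correction is
applied, matching the source analysis. The n ≥ 5 guidance for the normal
approximation is enforced as a warning, not an error, so degenerate
two-point examples remain computable.

The packaged fixture transcribes the published nine-NV measurement
matrix. Four statistics printed in the source do not recompute from its
own published integers (posttreatment FD-structure mean decrease 33 vs
30.0 recomputed, the NV-structure last-follow-up CI and mean sign, the
last FD-angio mean/SD/p) — presumably computed from unrounded source
data. They are flagged `consistent = FALSE` in the printed-statistics
fixture, reported with both values, and excluded from match assertions;
everything else reproduces exactly at printed precision. Since the source
publishes no absolute areas, the fixture's raw-area columns are
baseline-normalized (baseline = 1), which is sufficient for every
endpoint because area endpoints are relative.

## The synthetic generator

No OCTA volumes are published with the source cohort, so the generator is
the package's ground-truth instrument; every image-path claim in the
tests is made against it. It emulates:

* **Morphology** — a fan-like binary tree anchored on the ILM, spreading
  into the vitreous with tier-wise shrinking caliber and length, rendered
  as 3-D capsules (line + radius) so the voxel ground truth is exact.
* **Channels** — reflectivity raised along all segments over a two-layer
  background (dim vitreous, brighter retina); decorrelation raised only
  along perfused segments.
* **Treatment response** — a per-visit perfusion fraction mapped to
  generation tiers, distal tiers depressed first, because regressed NVs
  persist as truncated proximal arcs; the root tier never loses
  perfusion (the residual arc), and the scaffold is never deleted.
  Optional recurrence raises the fraction again from a set week.
* **Noise** — multiplicative unit-mean Rayleigh speckle on structure and
  additive clipped Gaussian noise on flow, a qualitative stand-in for OCT
  speckle; no physically accurate signal model, no motion or projection
  artifacts. Passing tests therefore certify the measurement arithmetic
  and its invariances, not robustness to real-device artifacts.

Defaults, chosen once as plausible for a 3 × 3 mm swept-source pattern:
256 × 256 × 128 voxels at 11.7 µm/px lateral and 6.3 µm/px axial, ILM at
0.75 · nz, branching depth 5, 40° azimuthal spread, speckle 0.15, flow
noise SD 0.05, visits at weeks 0/4/8/12/17/45 with perfusion fractions
1.0/0.8/0.5/0.3/0.25/0.2 and four monthly injections at weeks 0–12 (the
case-presentation regimen; week 17 sits 5 weeks after the last
injection). The source reports no quantitative NV morphology, so the
morphology parameters are stated as configuration, not as fact. One
global seed drives tree, jitter and noise; a fixed seed gives
bit-identical exported files.

Exported truth: per-visit delineations are convex hulls of the exact en
face footprints; truth areas are shoelace areas of those polygons; and
`true_perfused_fraction` is the fraction of structure-delineation pixels
covered by the perfused footprint — the ground-truth counterpart of
FD-structure. With noise off, measured FD-structure tracks it to well
under a percentage point; the acceptance checks allow ±5 points to leave
room for threshold-induced deviation at other seeds.

## Numerical choices and degenerate inputs

* 16-bit en face export; re-reading quantizes at 1/65535, far below any
  threshold decision at the rendered contrasts. 8-bit is also supported
  on input since the source leaves the export depth unstated.
* Empty delineation masks, zero baselines, all-zero difference vectors,
  sub-3-vertex polygons, slabs outside the volume, and windows larger
  than both image dimensions are errors, not silent zeros.
* The multi-channel TIFF reader rescales the [0, 1] values returned for
  RGB back to 8-bit units, because the underlying reader honours `as.is`
  only for single-channel images.
* ImageJ `.roi` support covers the polygon subtype (and freehand, read
  as a polygon); all other subtypes are rejected by name.

## Problem sizes

The unit tests run the generator at 96 × 96 × 48 voxels with depth 4 and
noise off — small enough that brute-force voxel oracles (exhaustive
rasterization, per-pixel sliding windows) stay exact and fast. The
analysis scripts and the acceptance script run the default
256 × 256 × 128 grid. The cohort statistics are desk-scale (n = 9) and
run in milliseconds.

## Known limitations

Manual delineation is taken as input, as in the source workflow —
no automated NV segmentation, no projection-artifact removal, no layer
segmentation. The nine NVs of the reference cohort include fellow eyes
and two NVs of one eye; the statistics treat them as independent, as the
source does, and no eye-within-patient correlation structure is modeled.
B-scan cohort numbers are deliberately not reproduced: single-slice
measurements are too alignment-sensitive for formal analysis, so the
B-scan path is validated against synthetic ground truth only.
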