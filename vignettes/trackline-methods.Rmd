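---
title: "Tracing objective footprint outlines along the steepest slope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing objective footprint outlines along the steepest slope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackline)
```

## The problem and the model

A fossil footprint rarely has a sharp edge. The foot deformed soft
sediment, so the footprint floor grades into the surrounding tracking
surface through a sloping *track wall*. Any 2D outline of such a track is
an interpretation, and hand-drawn outlines by different workers can
disagree substantially. `trackline` makes that interpretation a
deterministic computation: the outline is the locus where the track wall
is steepest — the inflexion of the wall profile, the margin criterion
most widely applied in ichnology — extracted from a triangulated 3D
surface model with no manual digitization.

The computation rests on three modelling ideas:

* **Contours reduce the dimension.** The full 3D wall is summarized by
  closed contour lines at equally spaced height levels; the outline lives
  somewhere inside this stack.
* **Homology before averaging.** Points on different contours must be
  matched perpendicular to the wall before any cross-level statistic is
  meaningful. Matching is anchored at *bottlenecks*, minimum-distance
  point pairs between the innermost and outermost contour, with the
  sections between bottlenecks resampled to matched point counts.
* **A weighted, not winner-take-all, steepness criterion.** The steepest
  level frequently fades out laterally and reappears at another height;
  snapping to the per-column maximum produces jagged, discontinuous
  outlines. Each homologous column therefore contributes the weighted
  mean of its per-level positions, with weights increasing with local
  steepness, and the resulting polygon is smoothed by a truncated
  elliptic Fourier series.

### Assumptions about the input

The model must contain a single complete footprint (or, with the
multiple-impressions option, a few separate impressions) plus a margin of
surrounding surface; the surface must be a height field over the tracking
plane at the scale of the footprint (photogrammetry and laser scans
satisfy this); and the model is assumed digitized viewing the surface
from above, the universal convention of field photogrammetry — this
assumption is what lets cast/mold conversion coexist with mirror
correction (below).

## Pipeline stages and their parameters

All coordinates keep the model's units (meters in the examples); no stage
rescales. Parameters live in `pipelineConfig()`; the defaults below are
used for every result in the package.

| parameter | default | role |
|---|---|---|
| `levels` | 30 | contour height levels, equally spaced strictly inside the z-range |
| `points` | 500 | points per contour for homologization |
| `harmonics` | 25 | elliptic Fourier harmonics of the final outline |
| `smooth_iters` | 10 | cyclic (1,2,1)/4 smoothing passes before the Fourier fit |
| `min_length_frac` | 0.5 | contours shorter than this fraction of the longest are trimmed from the ladder ends |
| `lower_area_ratio` / `upper_area_ratio` | 1.5 / 1.3 | area jump (larger/smaller) that truncates the stack below/above the middle contour |
| `weight_exponent` | 2 | steepness weight = (s / s_max)^exponent |
| `window` | 5 | ± columns searched on adjacent levels when measuring wall steepness |
| `digit_prominence` | 0.1 | radial prominence (fraction of radial range) for digit lobe detection |

Notes on the less obvious choices:

* **Level placement.** Levels sit at `z_min + i (z_max − z_min)/(n+1)`,
  `i = 1…n`: strictly interior, so the extreme levels are never empty.
  After orientation, z is referenced to the rim (median z of the outer
  10% of the bounding box is 0), which gives levels a stable physical
  meaning across models.
* **Area thresholds are ratios**, not absolute differences, which makes
  the rule scale-free; the lower half tolerates a slightly larger jump
  (1.5 vs 1.3) because floor contours legitimately shrink quickly.
* **Weight exponent 2** concentrates weight near the steepest level while
  preserving the defining property that equal steepness yields equal
  weight; exponent 1 underweights the inflexion zone and ≥4 approaches
  the jagged winner-take-all behavior the weighting exists to avoid.
* **The ±5-column window** exists because a homologous column is not
  exactly perpendicular to the wall, especially mid-section between
  bottlenecks; the minimal distance to *any* nearby point of the adjacent
  level approximates the perpendicular wall distance.

### Orientation, mirror correction, and casts

PCA of the vertex cloud maps PC1/PC2 to the tracking plane and PC3 to the
relief. Two sign ambiguities remain. First, the PCA basis can be a
reflection; this is detected threshold-free by comparing a deterministic
~100-vertex subsample against the fitted subset and its z-reflection
under ordinary Procrustes superposition (proper rotations only) and
keeping the closer orientation — equivalent to demanding determinant +1,
but expressed as the shape comparison it really is. Second, the relief
sign: a footprint is a central depression, so the median z of the central
25% of the bounding box is compared with the median z of the outer 10%
rim. An apparent bump can be either a genuine cast or a mold fitted
upside down; the two are distinguished by the direction of the fitted
z-axis in the *original* coordinates (face-up assumption above). Molds
are corrected by proper rotations only, so the outline's chirality is
preserved; a cast receives one reflection, which maps it onto the mold
that formed it — hence a z-negated copy of a mold reproduces the mold's
outline exactly, while an in-plane mirrored mold yields the mirrored
outline. Ties (|center − rim| below 1e-9 of the bounding-box diagonal)
are treated as molds and left untouched.

### Rasterization

Contours are extracted by marching squares on a regular grid interpolated
from the cloud. The interpolation is barycentric over the mesh's own
triangles — the mesh connectivity *is* a triangulation of the vertices,
so re-triangulating the projected points would only re-derive (or, on
concave boundaries, degrade) what the file already states. Grid pitch is
the median nearest-neighbor spacing of the vertices (so the grid matches
the model's own resolution), bounded below so the grid never exceeds
about 2000 cells across; the grid is anchored on the cloud's bounding-box
center so mirrored or rotated copies of a model are sampled at mirrored
node positions. Nodes outside the triangulated region are missing values,
which is what makes contours that leave the model come back *open* — and
open contours are exactly what the first selection rule removes.

### Homology details

Bottleneck 1 is the global minimum of the inner×outer distance matrix;
ties break toward the smallest outer, then inner, index (determinism over
geometry). Its homolog on an intermediate contour is the point closest to
the bottleneck *chord* — the segment, not the infinite line, which would
intersect an elongate contour a second time on the far side and make the
antipodal point an equally good pick. Bottleneck 2 is constrained to the
opposite side (outer index within n/8 of half a turn away); two more are
found per side; sections longer than twice the mean section arc are
subdivided further (up to three rounds). No bottleneck may fall within
n/16 of an accepted one. Section point counts are allocated
proportionally to the outer contour's section arcs and applied to every
contour, restoring n points in total with the bottlenecks at shared
indices.

### The Fourier smoothing and its parameterization

The outline polygon is smoothed by `smooth_iters` passes of the cyclic
(1,2,1)/4 kernel (the conventional pre-smoothing in elliptic Fourier
outline practice) and approximated by a truncated elliptic Fourier
series. The series is computed under the *uniform* per-vertex
parameterization (each edge advances the parameter by one unit), not
chordal arc length: the pipeline feeds the fit a polygon that has been
resampled to equal arc-length spacing immediately before, so the two
parameterizations coincide there, and the uniform form has the useful
property that an ellipse sampled uniformly in its affine parameter is
reproduced *exactly* by a single harmonic — a sharp correctness oracle
that the chordal form does not admit (under chordal parameterization the
x-coordinate of an ellipse is not a single harmonic of arc length, and a
1-harmonic fit of a 2:1 ellipse deviates by several percent no matter how
densely it is sampled).

Upright rotation maximizes, over integer degrees 1–360, the arc length of
the outline above its centroid (digit impressions need more outline
length than the heel), measured on a 720-point resampling; exact ties —
possible only for mathematically symmetric curves — resolve to the
smallest angle by the maximization's first-hit rule.

### Landmarks

Digit lobes are prominent circular maxima of the radial distance from the
centroid (prominence ≥ `digit_prominence` of the radial range); exactly
three must lie above the centroid or the outline is rejected as not
tridactyl. Lobes are separated at the deepest radial re-entrants between
them, and each lobe's segment is clipped symmetrically (in point count)
about its tip so an ill-defined outer boundary (e.g. the smooth transition
into the heel) cannot tilt the axis estimate. The digital axis direction
runs from the midpoint of the two flank points at equal Euclidean
distance from the tip to the tip — exact for a lobe with parallel flanks —
and the axis offset is the mean x after rotating the lobe upright. The
rotation refinement by the central axis is iterated (up to 5 passes,
stopping below 0.2°) because the axis estimate itself improves as the
outline straightens. Tips are the most distal axis–outline
intersections; hypexes the most proximal points between adjacent tips
relative to the tip-connecting chord; the heel the most proximal
central-axis intersection. Landmarks are reported in geometric order
(left → right in upright view): anatomical medial/lateral labels would
require knowing which foot made the track, which the geometry cannot
tell.

### Procrustes statistics

`gpaAlign()` is a standard partial GPA: center, scale to unit centroid
size, iteratively rotate (proper rotations) to the consensus until the
consensus changes by less than 1e-10 RMS. The consensus orientation is
made canonical — principal axis along y (the footprint mid-axis
convention), sign fixed by coordinate skewness — so results do not depend
on input order. `landmarkVariabilityY()` reports the standard deviation
(optionally variance) of aligned y-coordinates per landmark.

## The synthetic generator

`generateFootprint()` builds meshes from closed-form signed planar
distance fields d(x, y) — capsules for digits, a disk for the heel, their
union for the footprint — with the surface

z(x, y) = −depth · logistic(−d / wall_width).

The inflexion of this wall sits exactly on the zero level set of d, so
the curve the pipeline is supposed to trace is known analytically; that
is the reason for the logistic profile (a conical, constant-slope wall
has no distinguished locus and is kept only as a contour-extraction
oracle). Defaults describe a medium theropod-like track: length 0.3 m,
depth 10% of length, interdigital angles 30°, central digit longest,
wall half-width 1.3% of length.

Two generator choices deserve emphasis:

* **Soft union (webbing).** The shape union uses a log-sum-exp soft
  minimum with length scale `web` (default 3.5 wall widths). A hard union
  would leave zero-width interdigital slots; since the retained contour
  stack spans in-plane offsets of roughly ±3.5 wall widths around the
  inflexion locus, any hypex fillet smaller than that band disappears
  from the deeper contours and the steepest-slope locus stops being well
  defined there. The soft union emulates the sediment webbing that rounds
  real hypex regions and keeps the notch present on every contour — the
  regime the method is designed for.
* **Rule-based truth landmarks.** Ground-truth landmarks are the landmark
  *definitions* evaluated on the analytic truth curve (at 1000-point
  resolution), not the capsule skeleton: webbing genuinely rotates the
  visible lobe midlines away from the buried capsule axes, so no
  outline-based scheme can recover the skeleton, and the meaningful
  reference for validating the 3D pipeline is the rule applied to the
  exact curve. The 2D rule itself is validated independently through its
  symmetry and mirror-equivariance properties.

What the generator does *not* emulate: substrate rheology, displacement
rims, overprinting, digital pad and claw detail, anisotropic scanner
noise, and holes or non-manifold geometry. Passing the synthetic suite
therefore demonstrates correctness of the geometry pipeline under clean
to moderately noisy height-field conditions, not performance on every
taphonomic situation; on real material the same subjectivity caveats
apply as for any automated outline.

`perturbMesh()` supplies the controlled degradations used by the tests:
exact rigid motions and reflections, decimation (vertex clustering to
near the target, then exact shortest-edge collapse), transverse cracks,
and digit-tip infill. `generateTrackwayLandmarks()` emulates a trackway
sample: the truth configuration plus per-track y-jitter (hypexes twice
the tip jitter by default, reflecting their higher variability along real
trackways) and random rigid motion and mild scale that the GPA must
remove.

## Numerical and degenerate-input behavior

* Contour stack selection with no closed contour anywhere raises a "no
  footprint found" error; a single-contour stack passes through
  homologization with a trivial identity homology and a warning.
* A column whose steepness is zero everywhere contributes the unweighted
  mean with a warning.
* Exact ties (bottleneck distances, longest-contour selection, upright
  angles) resolve by documented index rules, so reruns are bit-stable.
* All randomness (vertex noise, trackway jitter) flows through a single
  integer seed with save/restore of the RNG state; generation is
  byte-reproducible and never perturbs the caller's RNG.
* Perfectly symmetric synthetic footprints make the first bottleneck
  degenerate (many near-minimal pairs); the invariance checks therefore
  use a left/right asymmetric footprint, as real feet are.

## Problem sizes used in the validation

The packaged validation works at desk scale, chosen to exercise every
code path at the resolutions the method targets: 20k–60k-face meshes for
accuracy checks (grid pitch then matches the default footprint's wall
width), one ~200k-face model against its 5,000-face decimation for the
resolution-invariance check, 13 tracks for the trackway statistics
(a typical single-trackway sample), and n ≤ 200 for the exhaustive
bottleneck oracles.

## Known limitations

* The outline height range depends on the area-trim thresholds; features
  outside the retained stack (e.g. a faint toe impression above the upper
  cut) are invisible to the outline.
* Shallow footprints whose impressions close no contour cannot be traced;
  the multiple-impressions option handles separate pads but does not
  merge them into one outline.
* Extramorphological features (cracks, infill) are traced as if they were
  anatomy; `perturbMesh()` exists precisely to study that sensitivity.
* The tracking surface is fitted as a single plane; strongly curved or
  tilted surfaces beyond one PCA plane fit are out of scope.
* Landmark placement supports tridactyl tracks only.
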