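---
title: "Concentric-ring SIFT matching and sparse SFM: methods and design"
author: "ringsift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concentric-ring SIFT matching and sparse SFM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringsift)
```

## The problem

Sparse 3-D reconstruction from a handful of views — two or three
photographs or tomographic/ultrasound slices of the same scene — rests
entirely on the quality of the 2-D feature correspondences between the
views. `ringsift` implements a complete correspondence-to-structure
pipeline: a SIFT-style detector, a compact 64-dimensional descriptor
built on Sobel gradient fields over concentric rings, two successive
mismatch filters (neighbourhood voting and trimmed RANSAC), and
two/three-view epipolar reconstruction. Every stage can be exercised on
synthetic fixtures with exact ground truth, so the package is fully
testable without external imagery.

## Detection

Images are converted to luminance (BT.601 weights), median filtered
(3x3 by default, edge-replicated) to suppress impulse noise, and fed to
a classical difference-of-Gaussian (DoG) scale space: `s = 3` intervals
per octave (`k = 2^(1/3)`), base blur `sigma = 1.6` on a grid that
assumes 0.5 px of native blur, octaves down to an 8 px floor. Extrema
among the 26 scale-space neighbours are refined by a quadratic fit;
low-contrast responses (below 0.03 on the 0–1 intensity scale) and
edge-like responses (principal-curvature ratio above 10) are discarded.
These are Lowe's classic settings; none of them is a free parameter of
the method under study, so they are adopted wholesale.

One numerical choice deserves note: the sub-pixel refinement moves to a
neighbouring cell only when the fitted offset exceeds **0.6 px** rather
than 0.5. An extremum centred exactly between two pixels (offset 0.5 in
each coordinate) otherwise oscillates between the two cells until the
iteration budget is exhausted and a genuine feature is lost; the 0.6
cutoff is the standard remedy.

## Gradients

All orientation and descriptor evidence comes from Sobel gradient
fields rather than finite differences. The first-order field is

$$G^1_\sigma = \sqrt{(G^1_{x,\sigma})^2 + (G^1_{y,\sigma})^2},$$

with $G^1_{x,\sigma}, G^1_{y,\sigma}$ the responses to the two 3x3
Sobel templates on the Gaussian layer at scale $\sigma$. A
*second-order* field re-applies the same templates to the magnitude
raster $G^1_\sigma$; it responds to curvature of the gradient magnitude
instead of raw intensity ramps, which suppresses the elongated edge
responses DoG detection is prone to. The second-order field drives both
orientation assignment and the descriptor by default
(`field_order = 2`, switchable to 1).

Two conventions are fixed deliberately. Direction is computed as the
quadrant-aware `atan2(Gy, Gx)` — only a *consistent* convention matters
downstream, and the two-argument form is the one that is well defined
in all quadrants. Pixels with zero magnitude get direction 0 by
convention; they carry zero weight in every accumulation, so the
convention is unobservable.

## The 64-dimensional concentric-ring descriptor

The neighbourhood of a keypoint is divided into **8 concentric rings**
of equal width around the keypoint; within each ring, gradient
magnitude is accumulated into **8 orientation bins** of 45 degrees
(linear interpolation between the two adjacent bins), with the bin
origin rotated to the keypoint's main orientation for rotation
invariance. Ring weights decay with distance,
$w(r) = \exp(-r^2/(2\cdot4^2))$ for ring index $r$, normalised so the
innermost ring has weight exactly 1 — the weights must be
distance-decreasing but their exact profile is otherwise a free choice,
and a Gaussian falloff with a scale of half the ring count is the
least-committal smooth option. The 64 values are scaled to unit
Euclidean norm (a single normalisation; no clamp-and-renormalise step,
which belongs to the square-grid descriptor family, not this one).
Pixels exactly on a ring boundary belong to the inner ring.

The ring width is 1 px at the detection layer's grid for a keypoint at
the base scale and grows proportionally to `sigma` (`scale_radius =
TRUE`), so the descriptor support is scale-covariant; with the 8-ring
layout the maximum radius is 8 px at base scale. A fixed-radius variant
is exposed for comparison but is not the default, because it breaks
matching across scale changes within an octave.

Orientation assignment uses a 36-bin magnitude-weighted histogram over
a Gaussian-weighted disc of radius `3 * 1.5 * sigma`, smoothed twice
with a circular 3-tap mean; peaks at or above 80% of the maximum spawn
duplicated keypoints (auxiliary orientations), so each descriptor has a
single reference direction.

## Initial matching and neighbourhood voting

Descriptor distance is the angle `acos(<u, v>)` between unit
descriptors. A candidate pair survives the nearest-neighbour
distance-ratio (NNDR) test when the best distance is below 0.8 of the
second best (Lowe's ratio), target keypoints are assigned one-to-one
(smallest distance wins), and candidates are sorted by distance — the
"matching quality" order used by the later trim.

The voting filter then asks, for each candidate pair $m$: do the
*other* matched keypoints sit at consistent relative positions and
orientations in both images? For pair $m$, form the row vector of
distances from $m$'s reference keypoint to every other matched
reference keypoint, and the analogous row in the target image; likewise
rows of orientation differences wrapped to $[0, 2\pi)$. Each row is
**mean-centered** and unit-normalised, and the dissimilarities

$$\mathrm{dot1} = 1 - \langle \hat d_{\mathrm{ref}},
\hat d_{\mathrm{tgt}} \rangle, \qquad
\mathrm{dot2} = 1 - \langle \hat\theta_{\mathrm{ref}},
\hat\theta_{\mathrm{tgt}} \rangle$$

lie in $[0, 2]$ and vanish for perfectly consistent geometry. The pair
is kept iff `dot1 < T_d = 0.4` and `dot2 < T_theta = 0.3`.

The centering step is this module's central design decision. Raw
distance rows are non-negative with a large common mean, so the inner
product of two unit-normalised raw rows is always close to 1 — without
centering, dissimilarity thresholds of 0.3/0.4 could never fire and the
filter would be inert (numerically, a 50 px planted mismatch reaches
`dot1` of at most ~0.07 on raw rows). After centering, the statistic is
one minus the Pearson correlation of the rows: consistent pairs stay
near 0, and planted mismatches separate cleanly at the stated
thresholds. Both statistics are invariant to global rigid transforms of
either image's keypoints, and `dot1` additionally to uniform scaling.

Sets of two or fewer candidates have no neighbourhood to vote with and
pass through unchanged (with a warning).

## Trimmed RANSAC

The surviving matches, still sorted by descriptor distance, lose their
worst `floor(0.2 N)` pairs (the trim interprets "distance" as the
matching-quality order — image-space distance between correspondences
has no meaning before a transform is estimated). RANSAC then samples 4
pairs at a time (rejecting samples with any collinear triple), fits an
exact plane-projective homography by DLT, and scores by the number of
pairs whose symmetric transfer distance (forward and backward, each) is
below 2 px. Iterations stop adaptively (confidence 0.995, capped at
2000); the best model is refit by Hartley-normalised least squares on
its inliers and re-classified until the inlier set is stable. The
returned inliers always satisfy the residual bound under the returned
matrix. With a fixed seed the output is bit-identical.

A homography is an approximation for a general 3-D scene; the stage is
retained as a *mismatch filter* ahead of epipolar estimation, not as a
scene model, which is why its threshold is generous relative to the
parallax the later stages exploit.

## Two- and three-view reconstruction

From the filtered correspondences: RANSAC eight-point estimation of the
fundamental matrix (Hartley normalisation, rank-2 enforcement,
Sampson-distance inliers at 2 px), the essential matrix
$E = K'^\top F K$ with singular values projected to $(s, s, 0)$, and
SVD decomposition into the four candidate poses, resolved by cheirality
(the pose placing the most triangulated points in front of both
cameras). The translation is scale-free and normalised to unit length —
the global scale of any reconstruction from images alone is arbitrary.

The decomposed pose is then polished by a 5-degree-of-freedom
Gauss-Newton descent on the Sampson residuals of $E(R, t)$ in
calibrated coordinates. This *two-view pose polish* is deliberately
retained while full bundle adjustment (joint multi-view refinement of
poses and structure) remains out of scope: the linear eight-point
estimate alone leaves translation-direction errors several times larger
than the polished result at realistic noise, and every downstream
quantity inherits that error.

Triangulation is linear DLT per point (the smallest right singular
vector of the stacked 4x4 system); points at infinity are flagged, and
points must have positive depth in their views and reprojection error
below the configured ceiling (2 px by default) to enter the cloud. A
third view is registered by robust DLT-PnP against the triangulated
structure: a deterministic trimmed least-squares fit with an adaptive
tolerance (three times the median residual of the full fit, floored at
the ceiling) plus a sampled RANSAC fallback with samples of 12 for
gross contamination — minimal 6-point PnP fits amplify structure noise
far too much to score consensus reliably. Once all poses are known,
every track is re-triangulated from all of its observations (stacked
multi-view DLT), which uses the widest available baseline. In the
geometry-only rig path (`reconstruct_rig`), three-camera arcs
bootstrap from the outer camera pair — twice the adjacent baseline —
and register the middle view by PnP, the usual initial-pair selection
rule of incremental structure from motion: the initial pair's
conditioning dominates the accuracy of everything built on it.

Intrinsics come from a user-supplied `K`; without one, the pipeline
falls back to focal `1.2 * max(width, height)` with the principal point
at the image centre and flags the output `approximate_k`.

## Synthetic fixtures: what they emulate, and what they do not

The generator provides three fixture families, all pure functions of
their arguments including the seed:

* **Textures** (`make_texture`): multi-octave filtered noise
  (histogram-equalised so blurred-noise's mid-weighted histogram does
  not starve the detector of contrast), separated Gaussian blobs with a
  per-blob detection guarantee, and checkerboard-plus-noise. The
  multi-octave mixture matters: a single-scale speckle texture loses
  essentially all its features under a blur-degradation fixture with
  `sigma ~ 2`, which is inside the stated robustness range.
* **Warp pairs** (`make_warp_pair`): rotation (up to ±30°), scale
  (0.8–1.25), projective, blur (sigma ≤ 2) and gamma (0.7–1.4)
  transforms with the exact homography recorded; a correspondence is
  *correct* iff `|H p - p'| <= 2` px, mirroring the RANSAC threshold so
  "matching rate" is well defined on fixtures.
* **Camera rigs** (`make_rig`): points in a unit-diameter volume at a
  depth of about 5 baselines, cameras 10° apart on an arc aimed at the
  scene centre, exact projections plus seeded Gaussian noise. The
  camera model is a calibrated DSLR-class sensor (3072x2048, focal
  2760 px — the capture geometry of the classic fountain benchmark).
  `make_relief_scene` renders actual images of a textured height-field
  by ray casting, with an exact pixel-to-surface ground-truth map, for
  end-to-end tests of the image pipeline.

Fixtures emulate geometric and photometric transformations with exact
ground truth; they do **not** emulate occlusion, repeated structure,
specularity, sensor noise models, or ultrasound speckle physics. A
passing fixture suite therefore demonstrates correctness of the
algorithmic chain under controlled conditions, not field performance on
clinical imagery.

Problem sizes used by the bundled verification suite were chosen to
characterise the estimators well while keeping runs interactive: 10
warp fixtures of 256x256 for matcher quality, 100 seeded runs of the
planted 24-inlier/6-outlier experiment, 20 two-view rigs of 150 points
at 1 px noise for pose recovery, and three 3-view rigs of 100 points at
0.5 px noise for structure recovery. The 0.5 px level for the 3-view
check is the localisation accuracy typical of a sub-pixel-refined
detector; at a full pixel of observation noise the narrow first-pair
baseline dominates the depth error budget and the 1%-of-diameter
criterion is no longer the informative scale.

## Degenerate inputs and failure modes

* Images smaller than 3x3, or with non-finite intensities, are rejected
  at construction.
* Fewer than 2 target descriptors: NNDR is undefined; all pairs pass
  with ratio 0 and a warning.
* Two or fewer voting candidates pass unfiltered (warning).
* RANSAC distinguishes "too few matches" from "no consensus" by error
  class; collinear minimal samples are redrawn.
* Identical views fail early with a low-parallax diagnostic (median
  displacement below 0.5 px) rather than returning a meaningless pose.
* Triangulated points at infinity (homogeneous scale ~0) are flagged
  and excluded; zero-baseline projection pairs are an error.

## Known limitations

* No bundle adjustment: with three views the result is a chained
  two-view + PnP solution, adequate at fixture noise levels but not a
  maximum-likelihood reconstruction.
* The homography-based mismatch filter can, in principle, discard
  correct correspondences on strongly non-planar scenes with wide
  baselines; the epipolar stage that follows is the safeguard.
* At most three views; no loop closure, no dense reconstruction.
* The descriptor has no affine adaptation; robustness is to similarity
  transforms plus moderate photometric change.
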