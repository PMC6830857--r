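---
title: "Methods: point-cloud cleaning, meshing and frame localization for endoscopic reconstructions"
author: "gastro3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point-cloud cleaning, meshing and frame localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

A monocular endoscope video of a hollow organ can be turned into a sparse 3D
model by an off-line structure-from-motion (SfM) tool, but the raw result is
unusable as is: capture hardware emits runs of duplicated frames that bloat
feature matching, the triangulated cloud contains large numbers of spurious
points, and a textured surface still has to be built from what survives.
`gastro3d` implements those surrounding stages — everything except SfM
itself, which an external tool provides as a `cameras/images/points3D` text
model.  All geometry is expressed in the arbitrary units of the
reconstruction; no metric scale is ever assumed, so every threshold in the
package is relative to the cloud's bounding-box diagonal `r`.

# Duplicated-frame removal

For a reference frame $I_t$ and a successor $I_{t+1}$ the statistic is the
fraction of pixels whose absolute difference is non-zero (a pixel of a
multi-channel frame differs if any channel does).  If that ratio is below the
threshold $\varphi$ (default 0.6), the successor is removed and the
comparison continues with $I_{t+2}$ and so on; the first frame at or above
$\varphi$ becomes the new reference.  The first frame is always kept, the
loop is idempotent, and $\varphi = 0$ keeps everything because the ratio
cannot be negative.

Comparisons run on raw 8-bit intensities with no normalization.  A
`zero_tolerance` parameter (default 0, i.e. strictly non-zero differences
count) is exposed because real sensors add noise that makes exact-duplicate
detection fragile; the default reproduces the strict rule.  Duplication is
observed per channel in practice, so the command-line front end deduplicates
a single channel after `split_channels()`; the loop itself is
channel-agnostic.

# The outlier-removal cascade

Cleaning proceeds through four stages, `P -> P' -> P^ -> P~`, each recorded
in a `cleaning_report`:

1. **Isolated-point filter.**  With `r` the bounding-box diagonal of the
   input cloud, any point whose nearest neighbour is farther than `A * r`
   (default `A = 0.05`) is removed.  The pass is single-shot: neighbour
   distances are measured once against the full input, so removals do not
   cascade.  `r` is recomputed on the survivors.
2. **Neighbourhood census.**  Each surviving point collects neighbours
   within radius `r` (the recomputed diagonal), keeping at most the 100
   nearest (`neighbor_cap`).  Points with fewer than `M = 80` in-radius
   neighbours are removed.  Taken literally, a radius equal to the whole
   cloud's diagonal makes nearly every point a neighbour, so the cap of 100
   nearest dominates; the radius is implemented literally, and a
   `radius_scale` knob (default 1) lets users shrink it if they want
   genuinely local censuses.  Equal distances at the cap boundary resolve to
   the lowest point index, for determinism.
3. **Local RANSAC plane fit.**  For each remaining point a plane is fitted
   to its neighbourhood by drawing random point triples (default 200
   iterations; degenerate, near-collinear triples count against the budget).
   No inlier criterion is standard here, so the package fixes the inlier
   band at `eps = 0.01 *` the local set's own bounding-box diagonal — a
   scale-free choice — and selects the candidate with the most inliers,
   breaking ties by the smaller sum of inlier distances and then by draw
   order.  When the iteration budget reaches the number of distinct triples
   the sampler switches to exhaustive lexicographic enumeration, which makes
   small fits independently verifiable against brute force.  The distance
   $D_i$ of each centre point to its own local plane is recorded; the mean
   of all recorded $D$ is computed once, over exactly the points that passed
   the census, and every point with $D_i$ strictly above that mean is
   removed.  The strict comparison means a perfectly planar cloud (all
   $D_i = 0$) loses nothing.
4. **Smooth-mesh filter.**  A deliberately low-detail surface is built from
   `P^` (the implicit reconstruction below at `smooth_mesh_depth = 5`), the
   unsigned point-to-mesh distance of every point is measured, and points
   farther than `B * sigma` (default `B = 5`) are removed, where `sigma` is
   the population standard deviation of the distance distribution.  `sigma`
   is floored at `1e-12 * r` so a degenerate all-on-mesh cloud cannot be
   wiped out by a zero threshold.

All tie-breaks are by lowest point id, all randomness flows from one integer
seed, and a fixed seed reproduces removal sets bit for bit.

## What the average-distance rule does on clean data

The plane-fit stage removes every point whose local plane distance exceeds
the mean.  That rule is effective exactly when the distance distribution is
outlier-inflated: spurious points push the mean far above the inlier mode,
so inliers survive.  On a cloud with no outliers the distribution is
homogeneous and the strict above-mean cut always removes the upper tail —
for a locally flat patch with Gaussian noise the distances are half-normal
and about 42% of points exceed the mean; at moderate densities the local
sets are curvature-dominated with a similar fraction.  The acceptance script
measures this directly (`clean_cloud_retention_pct`, about 58% on the
outlier-free fixture): the cascade is *not* harmless on already-clean
clouds, and this is a property of the published rule itself, not of the
implementation.  Users cleaning a cloud they believe is already good should
expect the plane-fit stage to thin it: there is no parameter that disables
the above-mean cut without changing the rule, so the honest options are to
accept the thinning or to run the stages individually and skip it.

# Normals and surface reconstruction

Per-point normals are the smallest-eigenvalue eigenvectors of the
covariance of each point's neighbourhood (the point plus its 100 nearest
neighbours), with signs fixed afterwards: a normal is flipped to point
toward the mean centre of the cameras that observe the point
(`dot(n, c_bar - p) >= 0`; an exactly orthogonal normal stays unflipped),
points without tracks use the globally nearest camera centre, and without
any reconstruction the fallback orients toward the cloud centroid — the
interior of the cavity, which is where the endoscope sits, so both rules
agree on intent.  Oriented normals are then smoothed by replacing each with
the renormalized mean over its 10 nearest points (including itself);
`k_smooth = 1` is the identity and a uniform field is a fixed point.

Meshing is an implicit reconstruction authored in the package: the signed
distance at a grid node is the Gaussian-weighted average, over the `k = 12`
nearest oriented points, of the signed distances to their tangent planes,
and the zero level set is polygonized by marching tetrahedra (each grid cube
split into six tetrahedra sharing a main diagonal, so faces between cubes
are consistent and shared edge vertices dedup exactly).  The `depth`
parameter plays the role of an octree depth: the grid has `2^depth` cells
along the longest bounding-box axis (padded by 5% of the diagonal).  Low
depths give very smooth, low-detail surfaces — which is precisely what the
cascade's stage 4 wants — and the default final mesh uses depth 7.  Far from
the samples the blended tangent-plane field can change sign spuriously;
`keep_largest = TRUE` keeps only the largest connected component, which
discards such blobs deterministically.  On 2000 noiseless sphere samples the
depth-6 mesh has an RMS vertex error below 0.5% of the radius (the
acceptance script recomputes this), and vertex counts grow monotonically
with depth.  The residual error at high depth is the tangent-plane blending
bias, of order the squared sample spacing times the curvature, so
refinement plateaus rather than diverges.

Per-vertex color transfer scores every registered camera for each vertex by
`s = cos(theta) / (1 + d / r_mesh)`, where `theta` is the angle between the
vertex normal and the direction to the camera, `d` the distance and
`r_mesh` the mesh bounding-box diagonal — a dimensionless score that
increases with orthogonality and proximity, since no standard formula
exists for "closest and most orthogonal".  Candidates must see the vertex
(in front of the camera, projecting inside the image); occlusion is not ray
tested by default because a single cavity has little self-occlusion.  The
winning camera's image is sampled at the projected pixel (nearest pixel;
projection uses the pinhole part of the intrinsics and assumes frames were
undistorted upstream, where the calibration tool applies the fisheye
model).  Vertices no camera sees get sentinel gray (128, 128, 128).  Full
texture-atlas packing is out of scope.

# Retrieval and localization

Similar-frame retrieval ranks the sequence by Euclidean distance
`d = ||f(I_r) - f(I_t)||` between global descriptors.  The descriptor
interface is pluggable: the built-in `"downsample"` method grayscales,
average-pools to 16 x 16, subtracts the mean and L2-normalizes (so it is
invariant to global brightness scaling and deterministic), and externally
computed vectors — e.g. CNN embeddings — can be supplied as a matrix, one
row per frame, keeping the same ranking contract.  The reference frame
appears at rank 1 with distance 0; it wins its zero-distance tie against
bit-identical duplicates, and all other ties break by frame index.  The
published retrieval depth is `N = 100`.

`localize_frame()` places a registered frame on the mesh by casting a
32 x 32 grid of pixel rays (configurable; footprint visualization does not
need per-pixel resolution) from the camera centre and recording first hits
— rays may start inside the mesh, as an endoscope does.  The coverage
fraction is the share of rays that hit.

# The synthetic scene generator

No clinical recordings ship with the package, so every quantitative claim
is made on generated scenes with exact labels:

* **Surface.**  A star-shaped radial surface
  `R(u) = r_ellipsoid(u) * (1 + a * sum of angular Gaussian bumps)` over
  unit directions, defaults: semi-axes `(3, 2, 1.5)` scene units
  (organ-like proportions), 12 bumps of relative height 0.06 and angular
  width 0.35 rad emulating coarse mucosal relief.  Star shape buys an exact
  radial signed distance, which every oracle downstream uses; anatomical
  realism is a non-goal.
* **Cloud.**  5000 inliers sampled over directions with radial Gaussian
  noise `sigma = 0.03` units (about 0.4% of the bounding box, a plausible
  bundle-adjusted triangulation error), truncated at `3 sigma` so the
  inlier label contract is exact; 500 near outliers at radial offsets
  uniform in `[5, 15] sigma` with random sign — far enough to be separable
  from truncated inliers, near enough to require the plane-fit stage; and
  500 isolated outliers rejection-sampled in a padded box so each lies
  farther than `A * r` of the final cloud from every other point, making
  the stage-1 oracle exact by construction.  The generator verifies all
  label contracts exhaustively before returning and fails rather than
  emit an ambiguous fixture.
* **Cameras.**  A smooth interior spiral (polar angle sweeping 12-168
  degrees over three turns) at 35% of the local radius, looking radially
  outward, 40 poses with 256 x 256 pinhole intrinsics and focal 70 px — a
  wide field of view, as endoscopes have.  Each camera observes its 400
  nearest visible inliers; points left with fewer than two observations are
  topped up from the nearest cameras that see them, and points not visible
  to two cameras at all are excluded from the export with a warning (none
  are, under the defaults).  Tracks and observations are cross-linked and
  revalidated on every read.
* **Frames.**  Procedural 8-bit noise images with planted duplicate runs:
  frames inside a run are bit-identical, and each new distinct frame
  differs from the previous one in exactly
  `round(perturbation_fraction * npixels)` pixels with values forced to
  change (default fraction 0.8, chosen above `phi` — the generator rejects
  ambiguous specs).  Frame content only needs to exercise the
  pixel-difference and descriptor code paths; nothing is rendered.

What passing tests on these scenes shows — and does not.  The generator
emulates the *geometry* of the problem (a closed noisy cavity, two outlier
mechanisms, interior wide-angle trajectories, duplicate runs), so it
validates thresholds, determinism, bookkeeping and the interaction of the
stages.  It does not emulate photometric texture, dye contrast, fisheye
distortion, motion blur, or SfM's correlated error structure, so a pass
here does not certify clinical-data performance.

# Problem sizes and budgets

The test suite runs the cascade at the documented study size (6000 points)
and the mesh fidelity sweep at depths 4-7 on 2000 sphere samples; the
acceptance script repeats the headline computations from scratch in about
two minutes on one CPU.  Neighbour searches are exact brute force in
compiled code up to these sizes, with a uniform cell grid accelerating the
dense SDF grid queries; all of it is single-threaded and deterministic.

# Known limitations

* The above-mean plane-fit rule thins already-clean clouds (analysis
  above); the package reports what each stage removed so the effect is
  visible rather than silent.
* The neighbourhood radius of the census stage is the full cloud diagonal,
  taken literally; `radius_scale` exists because that reading is
  suspiciously global, but no other interpretation is guessed.
* The implicit reconstruction is a blended tangent-plane distance field,
  not a screened Poisson solve: it takes the same oriented-point input and
  has the same smooth-at-low-depth / faithful-at-high-depth behaviour, but
  its refinement plateaus at the tangent-plane bias instead of converging
  further, and it does not guarantee watertightness on incomplete
  coverage.
* Color transfer is per vertex, not a texture atlas, and visibility skips
  occlusion testing by default.
* Retrieval with the built-in descriptor is a brightness-invariant global
  layout match; it is a stand-in interface for stronger learned
  descriptors, which can be plugged in as precomputed matrices.
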