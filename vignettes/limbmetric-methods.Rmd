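---
title: "Validating photogrammetric residual-limb models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating photogrammetric residual-limb models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`limbmetric` implements the computational stages of a smartphone
photogrammetry workflow for residual-limb modelling, and — more centrally —
the validation framework that certifies such a workflow against CT-derived
reference geometry at the tolerances prosthetic socket design requires.
This vignette explains the models, the tunable parameters, the synthetic
test bed, and the design decisions that were genuinely open.

All geometry is in millimetres; the limb axis is +z with the distal end at
z = 0, which makes "axial slices" well defined. Camera poses are
world-to-camera throughout (the trajectory dialect we export uses that
convention).

## Frame selection

Handheld video yields motion-blurred frames. Sharpness is scored as the
population variance of the 3×3 Laplacian response
`[[0,1,0],[1,−4,1],[0,1,0]]` over valid pixels, on Rec.601 luma for colour
input — a fixed, reproducible weighting. A frame is retained when its score
is at least `alpha` times the **median** score of its centred `window`
(clipped at the ends). The moving-window statistic is a declared choice, not
an inference: the median is robust to isolated blur spikes. Defaults
`window = 15`, `alpha = 0.9`, `maxFrames = 150` keep roughly 1–2 fps of
locally sharp frames from 30 fps video.

The rule is iterated to a fixed point on the surviving set, which makes
selection idempotent (re-running it on its own output is a no-op). The
iteration can only shrink the set and terminates immediately when local
sharpness is homogeneous; it matters only when removing blurred frames
raises a window's median enough to disqualify a borderline neighbour. The
50 % alpha-matte threshold is inclusive (≥ 0.5 is foreground) as a
deterministic tie rule. Video decoding itself is delegated to an external
decoder (`ffmpeg`) behind a thin adapter; codec handling is not this
package's contribution.

## Metric scale from fiducial tags

Consumer cameras give reconstructions of arbitrary scale. Printed square
tags of known side length anchor the scale:

1. **Single-tag pose.** A planar homography (normalized DLT) from the
   canonical tag corners to the detected pixels, decomposed into a rigid
   pose; cheirality is enforced through the corner winding (a view from
   behind the plane reverses it) and collinear corners are rejected.
2. **Two-stage PnP.** Stage 1 uses the visible tag with the largest
   projected area (the most reliable geometry); stage 2 refines the camera
   pose by nonlinear least squares over all visible mapped tags' corners.
3. **Joint map optimization.** Tag poses are initialized by a spanning tree
   of relative poses from shared images, then all tag poses (except the
   root tag, gauge-fixed to the identity) and all camera poses are refined
   jointly by Levenberg–Marquardt (MINPACK, maximum 200 iterations, tight
   tolerances) on the summed squared corner reprojection error, with Huber
   weighting (δ = 2 px, iteratively reweighted) against occasional corner
   misdetections. Metric scale enters solely through the tag side length.
4. **Similarity alignment.** The closed-form Umeyama solution between
   corresponding camera centres maps an SfM trajectory (arbitrary scale)
   onto the metric tag trajectory; the transform is applied to the model. A
   residual RMS above 5 mm warns about outlier camera centres but the
   transform is still returned.

Pose increments use axis-angle parameterizations. Because all rotations in
these problems stay far from the π singularity, poses are parameterized by
absolute axis-angle vectors rather than composed increments; with MINPACK's
internal differencing an incremental chart would add a re-baselining loop
without accuracy benefit at these problem sizes. Tag *detection*
(dictionary decoding, subpixel refinement) is prior work and lives behind
an adapter: tests and synthetic data inject exact pinhole projections
directly, with zero distortion so closed-form oracles stay exact.

## CT outer-shell extraction

The reference surface comes from micro-CT of printed phantoms (isotropic
0.1 mm voxels in the real protocol). Only the outer shell matters:

1. a **global** Otsu threshold (256 uniform bins between the volume's min
   and max, so the result is independent of acquisition bit depth)
   separates printed material from air;
2. per slab, background **propagation** (6-connectivity — conservative
   against diagonal leaks through thin printed walls) seeded at the slab's
   x/y faces, and at z faces only where they coincide with the volume ends,
   turns internal cavities into material; seeding interior slab z-faces
   would let a cavity that crosses a slab boundary surface inside the slab
   core, so those faces do not seed;
3. an exact signed Euclidean **distance field** (negative inside) is
   smoothed with a truncated Gaussian (σ = 1 voxel — enough to suppress
   voxel staircase while moving the zero crossing on flat regions by well
   under a quarter voxel);
4. the zero level set is extracted on a consistent 6-tetrahedron
   decomposition of each cell with linear edge interpolation and
   shared-edge vertex welding. The tetrahedral variant of the
   marching-family extractors avoids the 256-case ambiguous-configuration
   tables and is watertight by construction; it converges to the same
   isosurface. The mesh is then Taubin-smoothed.

Slabs default to 256 layers with a 32-layer overlap; cores split each
overlap at its midpoint, so every core value has full smoothing and
near-field distance support inside its slab. The per-slab smoothed distance
fields are assembled core-by-core into one global field before extraction:
this makes the weld across slab seams exact (identical shared-edge values)
and the watertightness check enforceable, which a mesh-level concatenation
of independently extracted slab meshes cannot guarantee when slab-local far
fields differ. Slab equivalence is still verified at the mesh level
(symmetric Hausdorff below half a voxel against single-slab processing).
Both smoothers default to the canonical shrink-compensating Taubin pair
λ = 0.5, µ = −0.53, 10 iterations; the surface-preserving Laplacian filter
runs 20 iterations with a 90° maximal per-iteration face-normal rotation
per vertex and pinned boundary vertices.

## Registration

Reconstruction and reference meshes are aligned rigidly in two stages.
The coarse stage voxel-downsamples both clouds (4 mm default), computes
FPFH descriptors (3 × 11 bins, radius 5 × voxel), fixes one nearest-
descriptor correspondence per source point, and runs a seeded RANSAC over
3-point samples with edge-length (10 %) and distance pre-checks,
0.999-confidence early exit, and a least-squares polish on the winning
consensus set. The fine stage is multi-scale point-to-plane ICP against the
*exact* triangle surface of the target (closest-point queries on a uniform
triangle grid, signed via angle-weighted pseudonormals), at scales
(4, 8, 30), (2, 4, 30), (1, 2, 30) — voxel size, correspondence cap, and
iteration cap — with Gauss–Newton steps and step halving so the objective
is non-increasing within each scale; convergence at relative RMS change
below 1e−6. Every random draw flows from an explicit seed through a local
xorshift generator, so registrations are bitwise reproducible.

A geometric caveat the validation design must respect: a **surface of
revolution is not uniquely registerable** (any azimuthal rotation is a
symmetry), and on a **cone** a uniform normal offset is nearly identical to
an axial translation, so rigid ICP legitimately absorbs part of a uniform
inflation there. The synthetic phantoms therefore carry an optional `crest`
— a localized anterior prominence (Gaussian in azimuth and height, 12 % of
the local radius in the validation battery) emulating the azimuthal
asymmetry every real residual limb has. Registration-recovery tests run on
crested phantoms; the inflation-recovery (MRE = δ) property is asserted on
the cylindrical, bulbous and ischial families, where a uniform offset is
orthogonal to the rigid-motion manifold, and not on the conical family,
where no algorithm could recover it.

## Clinical metrics

The region of interest runs from the distal limb end to the anatomical
landmark plane (Mid-Patellar Tendon for transtibial, the adductor/ischial
midpoint for transfemoral), supplied as a height along the limb axis.
Clipping cuts crossing triangles exactly at the plane and closes the
boundary with a planar fan cap, so ROI solids are closed and the cap area
equals the cross-section area; whether the reference protocol capped its
ROI volumes is not determinable, and capping is the convention here.

"Radial" error is implemented as the signed nearest-point surface distance
(sign from the reference outward pseudonormal), not as distance along rays
from a limb axis: the two coincide on the concentric convex geometries used
as oracles, and the nearest-point form stays well defined on ischial
geometries with undercuts where axis rays are non-injective. Angular error
uses the barycentric interpolation of reference vertex normals at the
nearest point, so a matching tessellation contributes no spurious
facet-level angle. Hausdorff is symmetric (the larger of the two directed
maxima, vertices against exact triangle surfaces). Quartiles are type-7
(R's default, interpolated) and stated so tests can be exact; SDs are
sample (n−1) SDs throughout. Perimeter slices sit at mid-bin heights
`landmark·(k−½)/10`; each slice takes the largest-loop perimeter only, so
handles or noise loops cannot inflate it. MDC uses the standard MDC95
constant 1.96·√2. Threshold boundaries follow the printed operators
literally: |MRE| ≤ 0.25 mm, IQR ≤ 0.4 mm and Hausdorff ≤ 1.8 mm inclusive;
RMSE < 1 mm, MAE < 4°, MDC < 3.5 % strict; |bias| ≤ 1 % inclusive.

Repeatability selects the medoid of a repeat set under the symmetric-RMS
surface distance (ties to the lowest index; the medoid's own zero distances
are included, reading "to all repeats" literally), computes per-vertex
sample SD, IQR and P95 of |d| (spread carries no sign at the 95th
percentile), and pools all vertex-by-repeat signed distances into a single
distribution whose SD yields the global MDC.

## The synthetic test bed

The phantom generator is the package's ground-truth source, emulating the
four validated limb archetypes: conical and cylindrical transtibial shapes,
a bulbous ("aqua") transfemoral shape with a distal Gaussian bulge, and an
ischial shape with a lateral sinusoidal centre offset plus a posterior
bulge — enough non-convexity to stress registration and nearest-point
signing. Cross-sections are lofted along +z and closed with planar fan
caps; with planar caps the cylindrical and conical families have
tessellation-exact closed-form volumes (prism/prismatoid) and perimeters
(chord sums), which the oracle tests rely on. A rounded distal cap would be
marginally more limb-like but would destroy those closed forms; the
trade-off went to exactness.

Controlled deformations displace vertices along outward normals (uniform
`deformRadial`, seeded Gaussian `addVertexNoise`); voxelization tests voxel
centres by z-ray parity with an optional carved spherical cavity; tag
scenes project exact pinhole corners with seeded pixel noise. The synthetic
battery deliberately does **not** emulate photometric reality — texture,
lighting, segmentation failures, SfM drift, lens distortion — so passing it
certifies the geometric and statistical machinery, not end-to-end
photogrammetric accuracy on real captures. The default validation scene
uses 4 tags (20 mm) on a 100 mm grid with 8 cameras at ~500 mm range and
4K-smartphone-like intrinsics (f ≈ 2800 px).

## Numerical choices and degenerate inputs

- Closed meshes with inward winding are auto-reoriented with a warning
  (wild STL files have mixed winding); degenerate faces are dropped at
  construction.
- Vertices exactly on a slicing or clipping plane are nudged by ~1e−12 of
  the coordinate scale for a deterministic intersection topology; exact
  zeros in the isosurface field are pushed to the outside by 1e−30.
- The Euclidean distance transform uses a large finite constant instead of
  IEEE infinity for empty scan lines (infinite parabola intersections are
  indeterminate).
- The Laplacian guard tests each vertex's own proposed move against its
  incident face normals with all other vertices held fixed, then applies
  all admissible moves simultaneously.
- RANSAC and vertex-noise randomness never touch R's global RNG state
  (local seeding, own PRNG in compiled code).
- Welding quantizes to the tolerance grid with neighbour-cell search, so
  exactly shared isosurface edge vertices always merge.

## Problem sizes

The shipped tests and the acceptance battery run on sizes chosen for a
single CPU: icospheres at subdivision 4 (2 562 vertices), phantoms at
64 × 40 (registration) or 48 × 30 (batch runs) resolution, CT volumes of a
20 mm sphere at 0.5 mm spacing (~86³ voxels), 8-camera/4-tag scenes, and
10 + 20 seeded trials for registration and tag-noise recovery. The
estimators are resolution-independent; these sizes keep the full suite in
the minutes range while leaving tessellation error an order of magnitude
below every asserted tolerance.

## Known limitations

- The SfM/MVS reconstruction chain itself (feature matching, bundle
  adjustment, densification) is external; this package scales, registers
  and scores its output.
- Rigid registration only — soft-tissue deformation between sessions is
  outside scope, as it is for the phantom-based protocol this package
  validates.
- ROI cap triangulation fans around the loop centroid, which assumes
  star-shaped cross-sections; extreme non-convex sections at the landmark
  plane would need a general polygon triangulator.
- The NRRD reader covers attached-header raw/ASCII/gzip little-endian
  scalar volumes — the common export of CT workstations — not the full
  format zoo.
- Printed-tag manufacturing error translates directly into model scale and
  is not modelled; the tag side length is taken as exact.
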