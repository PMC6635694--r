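---
title: "Methods: inertial body frames, donor-based reconstruction and sesamoid-groove quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inertial body frames, donor-based reconstruction and sesamoid-groove quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

BoneFrame analyses closed triangular surface meshes of individual foot
bones — typically segmented from CT at ~0.5 mm slice thickness — in
coordinate systems derived purely from the bones' own mass
distribution. This vignette records the models, conventions and
numerical choices behind each stage, and what the synthetic test suite
does and does not demonstrate.

## The solid model and its mass properties

Every bone is treated as the uniform-density solid enclosed by a
watertight, consistently oriented triangular surface; density is fixed
at 1, so masses are volumes (mm^3) and moments of inertia carry units
of mm^5. Whether real bone is internally uniform is immaterial here:
all downstream quantities (principal axes, extents, ratios) only assume
a *consistent* definition across subjects, and the segmented outer
surface provides one.

Volume, centre of mass and the inertia tensor are computed exactly by
signed-tetrahedron summation against the origin (the divergence
theorem): for a face with vertices $(a, b, c)$ the signed tetra volume
is $\det[a\,b\,c]/6$, its centroid $(a+b+c)/4$, and its second-moment
contribution $V_t/20\,(\sum_i v_{ip} v_{iq} + \sum_i v_{ip} \sum_j
v_{jq})$. The implementation is validated against closed forms (boxes,
spheres) and, on irregular synthetic bones, against an independent
brute-force oracle that voxelizes the solid at 0.25 mm and sums voxel
contributions; agreement is required within 1% (observed: ~0.05% for
volume, ~0.03% Frobenius for the tensor).

Non-watertight input is repaired at load time (exact duplicate vertices
merged, exactly-degenerate faces dropped, winding made consistent by
edge-adjacency flood fill, global orientation fixed by the sign of the
enclosed volume); if open edges remain, mass-property computation
refuses with the boundary edge count — reconstruction semantics need an
enclosed solid. Only *exactly* degenerate faces are dropped: tiny
sliver triangles produced by isosurfacing are legitimate parts of a
closed surface, and removing them would open holes.

## The body coordinate system

The body frame has its origin at the COM and axes along the principal
axes of inertia, ordered by ascending principal moment, so axis 1 is
the elongation (long) axis, axis 2 the wider transverse (width) axis
and axis 3 the vertical (height) axis. Principal axes are only defined
up to sign, so signs are fixed by a mesh-intrinsic convention: axes 1
and 2 are oriented so the third central moment (skewness) of vertex
coordinates along them is non-negative (ties: the farthest vertex made
positive), and axis 3 completes a right-handed triplet. The convention
is deterministic and needs no anatomical landmarks, but it cannot know
anatomical sidedness: medial/lateral labels downstream are therefore
relative, with an explicit `flipSides` override, and the reconstruction
stage re-resolves the four 180° flip candidates explicitly (below).

Near-degenerate principal moments (relative eigenvalue gap < 1e-6, e.g.
a sphere) trigger a warned fallback to the global axes; real bones
never reach this.

Length/width/height are axis-aligned bounding-box extents in the body
frame — the simplest reading consistent with a standardized length of
exactly 100. Standardization applies one uniform scale
`s = 100 / metatarsal length` to all three bones of a subject; the
packaged measurement table stores surface areas and volumes
post-standardization (scaled by $s^2$, $s^3$), which their magnitudes
imply.

## Morphometric ratios and donor choice

Each of the 15 measures (5 per bone) is divided by the reference
subject's value; ratios are kept at full precision and displayed at 4
decimals (round half up). The donor score is the arithmetic mean of a
subject's 15 ratios — the "smallest mean value" criterion — with all
measures weighted equally; principal moments are computed and reported
but excluded from the default score since the standard comparison
tables do not include them. A `mean_abs_dev` alternative (mean of
|ratio − 1|) is provided because "closest to the reference" admits that
reading; on the packaged data the two disagree (the mean-ratio score
selects the middle-distance runner, the deviation score a basketball
player), and the mean-ratio criterion is the method's own definition,
so it is the default. Ties break by input order with a warning.

## Reconstruction of a damaged bone

The donor and the damaged bone are first placed in their own body
frames, which aligns them up to the four proper 180° flips and a
residual error caused by the damage itself (missing mass shifts the
COM and tilts the axes — at 20–30% volume loss the naive overlap
leaves the donor several degrees and millimetres off). Both are
handled in one step:

* For each flip candidate, a trimmed rigid registration refines the
  pose: samples of the damaged surface are scored by their unsigned
  distance in a signed-distance field (SDF) of the donor solid, the
  worst 20% are trimmed (the damage cut faces have no donor
  counterpart), and Nelder–Mead minimizes over 3 rotation + 3
  translation parameters, coarse (0.5 mm grid) then fine (0.25 mm,
  trim 10%). Registration runs damaged→donor because the damaged
  surface is (cut faces aside) a subset of the donor's, not vice versa.
* Candidates are then ranked by *protrusion*: mean damaged-surface
  distance **outside** the donor solid, counted only above a noise
  floor of 0.6 voxel. Under the correct flip the damaged bone nests
  inside the donor and the score is ~0; under a wrong flip, smooth
  damaged surface spans the donor's carved anatomy (e.g. the sesamoid
  grooves) and protrudes by millimetres. Ranking is done only after
  the fine polish — an unconverged correct pose scores no better than
  a converged wrong one.

The pose stays rigid (plus the set-level uniform standardization
scale); no landmark correspondence and no shape warping are used.

Defect detection flags donor vertices farther than a threshold
(default 1 mm, twice the default voxel pitch) from the damaged surface,
grown by two one-ring dilations; the patch is reported as a donor-area
fraction. Completion is voxel-domain: on a shared grid (default pitch
0.5 mm, matching common CT slice thickness), the added region is the
donor-minus-damaged difference restricted to a defect *core* — voxels
deeper than the threshold inside the donor solid — plus its own skin
within a small neighbourhood (default 1.5 mm) of the core. Defining the
core by depth inside the *donor* fills arbitrarily deep defects while
rejecting the thin crust that residual registration error produces
along matched surfaces. The union is re-surfaced through a chamfer SDF
by marching tetrahedra, yielding a watertight mesh that follows the
damaged (original) surface away from the defect; `restoreScale` then
inverts the standardization. How donor and fossil surfaces should blend
at the defect rim is not prescribed by the overlap-and-borrow idea
itself; the voxel union is one robust realization and is reported as
such.

On synthetic bones with 5–30% of their volume clipped and the intact
twin as donor, the pipeline recovers volume within ~0.5% and body-frame
extents within ~1.8% across seeds (tolerance 2%).

## Groove curvature diameters and parallelism

The sesamoid grooves are modelled as partial cylindrical surfaces
wrapped on the plantar head. A cross-section plane containing the
vertical body axis, with normal near the long axis, cuts both grooves
as concave arcs. The *base level* — the orientation, rotating about the
long axis, of maximal cross-section area — fixes the vertical axis used
for the CD scan. (For a rectangular section the maximal plane contains
the diagonal, not the wider face; for elliptical sections it contains
the major axis. The scan is insensitive to this choice within a few
degrees.)

Arc extraction resamples the outer contour uniformly (400 points),
computes smoothed discrete turning angles, and keeps concave runs with
at least 5 points and 8° of total turning. Both grooves lie on the
same (plantar) side of the head, so the side filter defaults to the
side of the strongest concave arc; medial/lateral labels follow the
sign of the in-plane coordinate along the second body axis, with
`flipSides` to override. The curvature circle is the algebraic (Kasa)
least-squares fit; exact inputs are recovered to machine precision, and
a noisy quarter-arc (r = 10 mm, sigma = 0.05 mm, 100 points) is
recovered within 2% on every seed tested.

The scan rotates the section plane in 0.5° steps about the vertical
axis, pivoting at the groove-arc centroid so the plane keeps cutting
the groove. The minimal fitted CD over the scan is the groove's CD:
an oblique slice of a cylinder of radius $r$ fits a circle of radius
$\approx r/\cos^2\varphi \ge r$, so the minimum recovers the true
diameter, and its angle recovers the groove-axis skew. (The procedure
is sometimes described as seeking the *maximal* CD; the minimal-CD
criterion is the geometrically correct one for recovering a cylinder's
true diameter and is the default, with `scan = "max_cd"` available.) Because the objective is extremely flat near the minimum —
the CD changes by only ~$2r\varphi^2$ — the reported angle is refined
by a least-squares parabola over a ±2.5° window of the scan trace,
which averages per-section fitting noise and localizes the minimum to
roughly a third of a step; a 3-point refinement is not sufficient at
realistic mesh resolutions. Rotation sign is negative-clockwise viewed
from the positive axis.

Two grooves are *parallel* when their minimal-CD angles agree within
tolerance (default one step, 0.5°): both minima then lie in the same
cross-section and the joint has a single flexion axis. The equivalent
circle-vs-ellipse phrasing of dis-parallelism is implied by this
criterion (the off-minimum groove's section is elliptical) and is not
tested separately.

## The synthetic generator

`makeBone()` builds an implicit solid — a quartic superellipsoid shaft
(default 60 mm, semi-radii 9 × 7 mm) capped by a spherical head
(default radius 10 mm) with two cylindrical grooves (default radius
4 mm, carved to 0.8 of their radius, axes at ±35° from plantar,
skewable about the vertical axis) — evaluated on a voxel grid of pitch
`headRadius / (10 * meshResolution)` and isosurfaced by marching
tetrahedra. Ground-truth volume comes from the same grid's voxel
count (an oracle, deliberately not the surface integral under test);
groove CDs and angles are the construction parameters. Optional seeded
low-frequency bumps roughen the surface. Overlapping grooves are
rejected. Damage operators (`plane_clip`, `sphere_bite`) remove a
requested volume fraction — located by quantile/bisection on the voxel
occupancy, so the achieved fraction is exact to the grid — and re-close
the cut, like a real fossil break. Everything is deterministic given
parameters and seed.

What passing the synthetic suite shows: the geometry pipeline
(integration, frames, sections, fits, completion) is correct and
accurate on watertight, noise-controlled solids whose ground truth is
known. What it does not show: robustness to segmentation artefacts,
anatomical variation between donor and fossil (the real case borrows
across subjects; the suite's donor is the intact twin), cortical
thickness or internal structure, or the correct anatomical assignment
of medial vs lateral without operator confirmation.

## Numerical choices and degenerate inputs

* **Grids are cell-centred** with an irrational sub-pitch origin offset
  (fractions 0.2137…, 0.3703…, 0.4321… of the pitch). Isosurfaced
  meshes have many vertices and edges exactly on lattice planes;
  without the offset, parity rays used in voxelization strike them
  exactly and the occupancy collapses (observed as a 27% volume error
  at commensurate pitches).
* **Signed distance** is a 13-neighbour chamfer transform (weights 1,
  √2, √3) with the zero level midway between opposite cells; its few
  percent of directional anisotropy only perturbs surface placement by
  a fraction of a voxel.
* **Marching tetrahedra** (6 tetrahedra per cube) emits triangles
  oriented by the per-tetrahedron field gradient and shares vertices
  exactly via edge keys, so outputs are watertight and consistently
  outward by construction.
* **Sections** chain mesh–plane crossing segments by the exact mesh
  edge they cross (no tolerance matching); vertices exactly on the
  plane are perturbed by 1e-12.
* Ties: base-level ties return the smallest angle with a warning;
  donor-score ties return the first subject in input order with a
  warning. Zero steps, non-positive dimensions, empty sections, < 2
  concave arcs, collinear circle points and disjoint overlap inputs
  are all hard errors with specific messages.

## Problem sizes used by the tests

The unit suite generates bones at `meshResolution = 2` (0.5 mm
generator pitch, ~75k faces); the acceptance suite uses resolution 3
(0.33 mm) for groove recovery — 12 radius × skew combinations and 20
seeded parallelism pairs — 10 random bones against the 0.25 mm voxel
oracle, and 10 seeded clip-and-complete cases at 0.25 mm damage and
completion grids. The full suite runs in well under half an hour on a
single core; `scripts/acceptance.R` repeats the same studies in about
five minutes.

## Known limitations

* ASCII PLY only (STL ASCII/binary and OBJ are fully supported).
* The inertial sign convention cannot identify anatomical directions;
  side labels are consistent within a mesh but need `flipSides` when
  absolute sidedness matters.
* The completion surface carries voxel-grid texture at the patch;
  smoothing is deliberately not applied outside the defect, and the
  defect skin is reproduced at grid resolution.
* Groove skew recovery assumes grooves deep and long enough to yield
  ≥ 5-point arcs over the scanned range; very shallow grooves (< ~0.3
  of the radius) fall below the turning-angle threshold.
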