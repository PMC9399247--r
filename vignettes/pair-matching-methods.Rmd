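---
title: "Contralateral pair matching of anterior teeth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contralateral pair matching of anterior teeth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a maxillary anterior tooth is lost, an implant restoration looks and
functions best when its crown and emergence profile (the contour where the
tooth emerges through the gingiva) reproduce the patient's own anatomy. The
natural template is the contralateral tooth: central incisors, lateral
incisors and canines occur in near-mirror-image pairs across the midline.
`toothmatch` quantifies how good that template is. It takes triangle meshes
of individual teeth, mirrors the contralateral tooth, superimposes the pair,
scores the residual shape difference with the symmetric Hausdorff distance
(HD), and calibrates an HD threshold that separates true bilateral pairs
from pairs assembled across individuals.

## Pipeline

For one comparison between a right tooth and a (possibly different
individual's) left tooth of the same type:

1. **Mirror.** The left tooth is reflected across the plane that contains
   its long axis — the line through the root apex and the crown midpoint —
   with the mirror normal along the local mesiodistal direction. The
   literature leaves the azimuth of the mirror plane unspecified; because
   the subsequent registration step removes rotation about the axis, the
   choice only affects the initial condition, and we fix it to the
   mesiodistal direction of the local tooth frame (overridable).
2. **Landmark superimposition.** A closed-form least-squares rigid fit
   (cross-covariance SVD, reflections excluded) of the three reference
   points: root apex and the two most prominent incisal-edge points.
3. **Constrained ICP.** A point-to-plane iterative closest point refinement
   restricted to a 3-parameter family: rotation `theta` about the long axis
   and translation `(u, v)` in the plane perpendicular to it. The mirrored
   pair already shares a long axis by construction, so the residual freedom
   worth optimising is spin about that axis and in-plane shift; leaving the
   other three degrees of freedom fixed prevents the refinement from
   undoing the anatomically meaningful superimposition. Each iteration
   samples source vertices, finds nearest target vertices with
   area-weighted vertex normals, rejects correspondences beyond a cap
   (default 2 mm), solves the linearised point-to-plane normal equations in
   `(theta, u, v)`, and composes an exact in-family update (Rodrigues
   rotation about the axis line), so the accumulated transform satisfies
   the constraints to machine precision regardless of iteration count.
   Nearly rotation-symmetric teeth (canines especially) leave the spin
   about the long axis ill-determined by the surface alone — profiling the
   point-to-plane objective on synthetic canines shows spurious minima a
   fifth of a radian from the truth — so the population pipeline also
   feeds the three landmark correspondences into the least squares at a
   fixed fraction of the total weight (`anchor_weight`, default 0.6 in
   `run_match()`, calibrated against the known-truth registrations of
   mirrored pairs). Plain `constrained_icp()` is unanchored by default.
4. **Element separation.** The crown is the region coronal to the gingival
   margin curve; the emergence profile is the band between the margin and
   its 3 mm geodesic offset on the apical side; the root remainder is
   excluded from scoring.
5. **Scoring.** The symmetric Hausdorff distance
   `max(h(A,B), h(B,A))`, `h(A,B) = max_{a} min_{b} |a - b|`, between the
   two registered element surfaces. HD is deliberately computed between
   *point sets*, not point-to-triangle distances. `sample_surface()`
   represents a surface as its mesh vertices plus optional area-weighted
   uniform random face samples (default 10 points/mm²). The population
   pipeline, however, scores the *corresponding vertex sets* of the
   equally-tessellated meshes plus element boundaries densified at 0.15 mm
   (`density = 0` in `run_match()`). The reason is a property of HD between
   finite samplings: two *independent* random samplings of the same
   surface are Hausdorff-distant by their covering radius (~0.4 mm at 10
   points/mm²), so random resampling imposes a floor that masks
   sub-0.1 mm bilateral asymmetries; corresponding samplings have no such
   floor, and the boundary densification removes the analogous
   tessellation dependence of the cut polylines. Random densities remain
   available to probe sensitivity when comparing meshes of unequal
   resolution.

Across a population of `n` individuals, pairing is one-directional (right
versus mirrored left): the `n` same-individual comparisons are the true
("symmetric") pairs and the `n(n-1)` cross-individual comparisons the
negatives. A receiver operating characteristic is computed per tooth type
and element over the observed HD values (a pair is called a match when
`hd <= t`, ties inclusive), and the operating threshold is the **largest
threshold retaining 100% specificity** — equivalently, the point of maximal
sensitivity with zero false positives. Read literally, "the minimum HD at
full specificity" would be a useless threshold below all observations; we
interpret it as the full-specificity operating point and flag the
degenerate case where even that admits no true pair. Thresholds are
calibrated and evaluated on the same population (no held-out split), which
reproduces the calibration protocol this design follows; a user wanting
generalisation estimates should split by individual.

## Geometry internals and numerical choices

* **Geodesic distances** are multi-source shortest paths on a
  Steiner-refined edge graph: `k = 3` evenly spaced extra nodes per mesh
  edge, with every pair of boundary nodes of each face joined by its
  Euclidean chord. On smooth tooth-sized surfaces this is accurate to
  about 1–2% (verified on planes and cylinders where geodesics are known in
  closed form), which is adequate for a 3 mm offset; `k` is configurable.
* **Offset curves** are extracted as the iso-contour of the signed geodesic
  field by marching-triangles interpolation and chained into a closed
  polyline. Sides of a separating curve are determined topologically (flood
  fill over face adjacency blocked at curve-containing faces, widened by
  one face ring if the curve grazes vertices), not by coordinate
  heuristics.
* **Element boundaries split faces.** Faces straddling a region boundary
  are cut along the interpolated zero level of the signed geodesic field of
  the bounding curve (one new vertex per crossed edge, shared between
  neighbours), so crown + emergence profile + root is an *exact* partition
  of the refined face set: areas sum to the total within floating-point
  error. The cut follows the interpolated level set, which stays within one
  face of the annotated polyline — at working resolutions well below the
  anatomical variation being measured.
* **Curve annotation** uses periodic cubic splines with chord-length
  parameterisation through ordered control points, densely sampled (default
  200) and projected to the surface by exact closest-point-on-triangle
  queries.
* **STL dialects.** The binary dialect stores float32 coordinates (per the
  format), so binary round trips are exact only to single precision; the
  ASCII writer emits full doubles. Facets are welded at 1e-6 mm on read.
* **Degenerate inputs** (collinear landmark triplets, coincident axis
  points, empty meshes, open curves where closure is required, offsets that
  leave the surface, curves closer than one face apart) raise errors rather
  than propagate silently.
* **Nearest-neighbour searches** (ICP correspondences, Hausdorff, surface
  projection) run in compiled code on a kd-tree; the Hausdorff path is
  verified in the test suite against an exhaustive double loop — exact
  agreement, not approximate.

## The synthetic population

No real scan collections ship with the package, so study-scale experiments
run on a seeded generator of bilateral tooth populations. Each tooth is a
watertight surface of revolution-like solid: a tapering single root (apex
at the origin) blending into a superellipse-section crown along the +z long
axis, with a cervical bulge, incisally tapering faciolingual width (blade
form for incisors, a more pointed, strongly tapered crown for canines), and
a scalloped gingival margin (sinusoidal in the angular coordinate, peaks
interproximal) at the cervix. Typical crown/root dimensions follow standard
dental anatomy tables (e.g. central incisor: 10.5 mm crown, 13 mm root,
8.4 mm mesiodistal width).

Individuality enters as a smooth low-order radial deformation field —
angular harmonics up to order 2 times quadratic axial polynomials, 15
coefficients — drawn per individual and tooth type from
`Normal(0, sigma_pop²)`. Left teeth are exact mirror images of the same
individual's geometry plus an extra deformation drawn from
`Normal(0, sigma_asym²)`: the bilateral asymmetry. Asymmetry is modelled as
smooth deformation rather than vertex noise deliberately: real bilateral
differences are smooth anatomical differences, and HD against white-noise
vertices would measure mesh resolution, not shape. Defaults are
`sigma_pop = 0.5 mm` and `sigma_asym = 0.05 mm`, chosen so that
cross-individual element HDs land in the 1.5–4 mm range — the regime of the
reported clinical thresholds (≈1.9–2.5 mm) — while within-individual HDs
stay a few tenths of a millimetre.

What the generator does *not* emulate: restorations, wear facets, caries,
interproximal contact flattening, scanning noise and segmentation artifacts,
or population covariance structure learned from real teeth. Passing tests
on this population therefore demonstrate that the *pipeline* separates
small smooth asymmetries from larger inter-individual differences; they do
not certify clinical performance on scanned dentitions.

## Problem sizes and reproducibility

The package-default experiment (and the bundled acceptance script) uses 50
individuals at 32 × 32 mesh resolution per tooth — 7,500 ICP registrations
and 15,000 element HDs — which runs in minutes on one core; the
inter-individual/asymmetry contrast, not the mesh density, drives the
result, and coarser meshes mainly add a constant discretisation floor to
all HDs that the threshold calibration absorbs. Property tests use 10–24
individuals at 24 × 24. The population match loop defaults to 600 ICP
sample points and a 1e-4 mm convergence tolerance (against 2000 and 1e-6
for single high-accuracy registrations), which changes recovered motions by
far less than the HD discretisation floor. Every stochastic step (shape
draws, surface samplers) derives from one top-level seed; regenerating a
population with the same configuration is byte-identical, including the
on-disk manifest.

## Known limitations

* Constraint semantics: which axes the clinical protocol fixed in its
  "constrained ICP" is stated only loosely in the literature; the
  axis-spin + in-plane-shift reading implemented here is recorded as an
  interpretation, and the mirror azimuth likewise.
* The ROC negatives use all `n(n-1)` cross pairs; with strong class
  imbalance the full-specificity threshold is conservative.
* Geodesic offsets inherit the ~1–2% graph-metric error; at 3 mm this is
  tens of micrometres, far below anatomical variation, but it scales with
  offset distance.
* Mesh element extraction assumes the margin and offset curves are at
  least one face apart; meshes much coarser than the 3 mm band width are
  rejected rather than guessed at.
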