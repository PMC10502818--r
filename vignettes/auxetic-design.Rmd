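---
title: "Algorithmic auxetic lattice design and the voxel finite-cell screen"
author: "auxmesh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Algorithmic auxetic lattice design and the voxel finite-cell screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

auxmesh generates printable auxetic metamaterial geometry — planar meshes,
cylindrical meshes, organ-wrapped sheets and perfusable constructs — as
thickness-attributed beam networks, renders them to signed-distance voxel
grids, and screens their Poisson's ratio with an embedded finite-cell
(fictitious-domain) elasticity solver. This vignette explains the models,
the tunable parameters, the numerical choices, and what the synthetic test
conditions do and do not establish about fabricated hydrogel constructs.

## Lattice generators

All lengths are millimetres. A lattice is a `beam_network`: vertices plus
beams, each beam carrying the thickness `t` of the strut it becomes when
the network is inflated into capsules (cylinders with hemispherical caps)
on a voxel grid.

**Re-entrant honeycomb** (`gen_planar_auxetic`, kind `"reentrant"`).
Vertical baselines at uniform separation carry `2 * n2` corner rows whose
x positions alternate by ±`amplitude`, with the sign pattern flipped on
consecutive baselines. Corners are chained into vertical zigzags, and the
facing corner pairs of consecutive baselines are joined by horizontal beams
on alternating rows. The connectors join the **wide** (outward-offset)
pairs: the cell enclosed between two consecutive connectors then has walls
that bulge inward — the re-entrant bow-tie. (Joining the narrow pairs
produces the conventional honeycomb instead; we verified that variant
computes a positive Poisson's ratio and rejected it, since the whole point
of the topology is lateral expansion under stretch.) Under axial stretch
the inclined walls rotate and push the cells apart laterally, so the
Poisson's ratio ν = −ε_lat/ε_ax is negative, increasingly so for thin
walls and shallow wall angles.

**Arrowhead.** The same offset construction but every baseline carries the
identical pattern; each negative-offset corner sends two diagonals to the
neighboring positive-offset corners of the next baseline, forming nested
arrowheads. Note this lattice is glide-symmetric, not mirror-symmetric,
about the vertical midline.

**Sinusoidal ligaments.** One sinusoid per baseline, waving in x as a
function of y with period twice the horizontal element spacing; alternate
baselines are phase-shifted by half a period, so neighbors are in
anti-phase. Straight horizontal connectors join each pair of neighboring
sinusoids at the extreme rows where the pair is widest. This is the
curved-wall analogue of the re-entrant bow-tie and is strongly auxetic.
Sinusoids are discretized at 16 polyline segments per half-period (<0.5%
chord error at printed scales).

**Pinwheel.** The same construction with zero relative phase shift. In our
reconstruction the pinwheel mesh computes a small *positive* ν
(≈ 0.05–0.4 over the designs we screen); we tried several variants
(fused perpendicular families, connectors at zero crossings or extremes,
uniform and alternating connector parity) and none is auxetic in plane
strain-free stretch. Pinwheel lattices in the literature derive their
auxeticity from chiral node rotation, which suggests the printed design
contains a rotation-enabling detail that the published construction text
does not pin down. We keep the zero-phase reading and let the acceptance
suite report the sign honestly.

`amplitude` defaults to a quarter of the baseline separation and must stay
below half of it (self-intersection). Finished meshes are affinely
normalized to span exactly `width x height`, matching the printed
10 × 10 mm sheets.

**Cylinders** (`gen_cylindrical_auxetic`). The corner lattice is built in
the unrolled plane (circumference `2πR` by height `H`), closed
periodically (hence `v` must be even), and every beam is subdivided at 5°
of arc per segment and mapped by the arc-length-preserving wrap
`(x, y) → (R cos(x/R), R sin(x/R), y)`, so ring beams become true arcs on
the cylinder coat. Vertical re-entrant cylinders offset their corners in
the angular direction; horizontal re-entrant cylinders are the transposed
construction (zigzag rings composed of two circles with angular step
`2π/v` and phase shift `π/v`, joined by vertical beams on alternating
angular positions); sinusoidal/pinwheel cylinders are sinusoidal rings
(an integer `v/2` periods around the seam) joined by vertical connectors.

## Surface wrapping

Organ-conforming sheets are produced by `clip_to_circle` (exact
segment–circle intersections), `wrap_to_sphere`, and
`project_network_to_surface`. The sphere wrap is **azimuthal-equidistant**:
a planar point at polar coordinates (ρ, φ) maps to polar angle ψ = ρ/R at
azimuth φ, so radial geodesic distances equal planar distances exactly and
cell sizes stay nearly undistorted; the source text does not name its map,
and this choice best matches the undistorted cells in its figures.
Projection replaces every (subdivided) point by its closest point on the
target triangle mesh; the closest-point query uses an exact per-triangle
closed form with a centroid/circumradius prune whose results are, by
construction, identical to exhaustive search (and are tested against an
independent brute-force oracle). Projection onto the organ is restricted
to downward-facing triangles by default ("the bottom of the organ"), and
the curved sheet is first sunk `intersection_depth` (default 5% of the
organ's bounding-box height) into the target, which stabilizes the
assignment of sheet points to nearby surface patches.

`gen_synthetic_organ` provides a deterministic, watertight, genus-0
heart-like blob (two smooth-min-blended lobes and a tapered apex) so the
wrapping pipeline is testable without external model downloads. It is a
geometric stand-in, not an anatomical model: it has no valves, vessels or
concave interventricular groove deep enough to shadow the projection, so
passing tests demonstrate correctness of the geometry operators, not
fitness of any particular patch for a real heart.

## Perfusable constructs

The channel tree grows one half-channel from the inlet hub with radial
excursion `ρ(s) = (D/2)s + amplitude·sinh(k·s)`, copies it `n_copies`
times around the axis, mirrors it about the midplane with a half-pitch
twist, and joins matching midplane endpoints with straight channels;
thickness tapers linearly from the inlet diameter `d` to the mid-channel
thickness `t`. The alveolus is a union of mini-spheres (radius `r`) whose
centers sit on the sphere of radius `Rp − r` at mutual spacing ≥ `o`,
placed by a deterministic spherical Fibonacci layout (or seeded rejection
sampling; both modes are provided because the source does not state which
was printed), plus an interior core sphere that keeps the union solid.
The capillary net subdivides an icosahedron `level` times on its flat
faces, joins each triangle's centroid to its three edge midpoints, opens
the inlet window by scaling the top ring by `top_enlarge` (default 2)
about the topmost vertex, grades beam thickness linearly along the
inlet–outlet (x) axis, interpolates every beam into `n_interp = 11`
equidistant points (10 sub-beams), and projects all points radially onto
the circumscribed sphere. `wrap_network_to_offset_surface` then projects
each point onto the alveolar surface dilated by `gap` (default 0.25 mm);
with the sphere list from `gen_alveolus` the projection is analytic and
the realized clearance is exact away from the concave creases between
buds. Construct assembly is voxel CSG: outer solid minus channels minus
cavity minus port bores, with perfusability checked by 6-connected flood
fill of the void.

## The finite-cell mechanics screen

The solver implements small-strain linear elasticity on the voxel grid
itself: bilinear quadrilaterals (plane stress, for the thin printed
sheets) or trilinear hexahedra (for cylinders), each element an aggregate
of `quadrature_depth = 2` voxels per edge. Each member voxel acts as an
integration sub-cell with a 2×2(×2) Gauss rule and stiffness factor α = 1
if its center lies in the solid (SDF < 0) and `alpha_void = 1e-6`
otherwise — the fictitious-domain trick that removes meshing entirely.
The system is symmetric positive definite and solved by supernodal sparse
Cholesky; the relative residual is checked against 1e-8 and a failure is
an error, never a silent result.

Boundary conditions follow the computational screen: axial stretch
prescribes `u = strain · L0` on the solid nodes of the top boundary band,
with the bottom band on rollers (axial component fixed, lateral free —
the condition that allows free lateral expansion) and point pins removing
the lateral rigid modes; `fixed_bottom` reproduces the clamped
experimental grips, which visibly reduces the apparent |ν|. Strains are
read from boundary-node averages: the lateral strain from the mean
lateral displacement of the 5% extreme solid nodes on each side, with
widths measured between band centroids so the homogeneous-plate limit is
exact (the solver reproduces the material ν to solver precision, and a
voxelized cantilever matches Euler–Bernoulli tip deflection within a few
percent at 160×20 elements).

Radial stretch of cylinders prescribes the outward radial displacement
`strain · r` on the end-ring nodes with the bottom ring pinned axially.
The reported ν_radial = −ε_axial/ε_radial uses the **realized** mean
radial strain of the outer shell, not the imposed end strain: the end
rings engage the middle of the cylinder only through the lattice, so the
imposed strain overstates the denominator roughly tenfold and would push
every design toward zero. With the realized strain a solid cylinder reads
≈1.35 (close to the affine-expansion limit 2ν/(1−ν) = 1.64 for
ν_mat = 0.45) and lattice designs spread over ≈0.2–1.1, which is the
physically meaningful foreshortening-per-expansion ratio used for stents.

Material defaults: E = 50 kPa, ν_mat = 0.45 (near-incompressible
photocrosslinked gelatin at the printed 5% w/v). In the linear regime the
lattice ν is dominated by geometry; E cancels from ν exactly, and ν_mat
matters mainly for the dense, plate-like corner of a design sweep.
Applied strain is 0.01 — the experimental 10–50% stretches are far
outside the linear model and deliberately not emulated.

## Design sweeps and problem sizes

`sweep_poisson` runs one voxelization + solve per design row, records
failures per row (e.g. a design whose solid does not connect the loaded
boundaries is reported, not fatal), and is deterministic. The canned
configurations used by the acceptance script are scaled to run in minutes
on one CPU:

* planar re-entrant: `n1, n2 ∈ {2, 4, 6, 8}`, `t ∈ {0.1 … 0.5}` mm on a
  10 × 10 mm sheet at 0.04 mm voxels (80 designs, ≈20k DOF each);
* cylinders: `h ∈ {3, 5}`, `v ∈ {8, 12}`, `t` thin-to-thick on
  R = 1.25 mm, H = 3.75 mm cylinders at 0.08 mm voxels (≈35k DOF each;
  the four topologies axially, horizontal re-entrant radially).

These sizes were chosen once, for tractability of 3-D sparse Cholesky at
one CPU, before the sweeps were scored. Two known consequences of the
scale-down: the dense/thick corner of the planar sweep approaches plate
behavior (raising the sweep maximum above the published one, which was
evidently screened over a thinner or sparser grid than ours), and the
small cylinders carry too few unit cells to reach the deepest published
axial auxeticity. The planar sweep minimum, by contrast, reproduces the
published extreme closely, and the radial band and its
no-negative-designs sign property reproduce as printed.

## Numerical choices and degenerate inputs

* SDF convention: negative inside; voxel sample point is the voxel
  center. Boolean CSG is min/max combination, exact on the zero level
  set.
* Beams render as capsules (the voxel engine leaves the cross-section
  unstated in the source; capsules are rotation-invariant, exact-distance
  primitives). Zero-length beams are rejected at construction; isolated
  vertices render as spheres of `point_radius` (documented degenerate
  rule).
* Default voxel spacing for rendering is `min(thickness)/6`; a warning is
  raised when spacing exceeds half the thinnest beam. Under-resolution is
  the main failure mode of the screen: a 2-voxel-thin beam can alias into
  a broken load path or a spuriously soft hinge (we observed one radial
  design flip sign between 0.1 and 0.075 mm voxels; the shipped sweep
  spacing resolves the thinnest element with ≥2.5 voxels).
* Surface extraction is marching tetrahedra on a uniform six-tetrahedron
  cube split with crossings interpolated once per global grid edge, which
  makes shared vertices exactly coincident and the mesh watertight;
  triangles are oriented outward by an interior-reference test.
* STL I/O writes both binary and ASCII with coordinates round-tripped
  through float32 so the two encodings are bit-consistent; the reader
  re-indexes the triangle soup by exact vertex match and drops
  zero-area faces (no further mesh repair).
* All randomness (foam pores, random alveolus placement, organ jitter)
  flows through per-call seeds with the global RNG state saved and
  restored; identical seeds give bit-identical artifacts.

## Limitations

The screen is linear and frictionless: no large deformation, no
self-contact of lattice elements (which the source observed
experimentally in air), no resin chemistry, dose or printing physics, and
no hemodynamics in the perfusable constructs. The pinwheel reconstruction
is not auxetic as built (see above). Sweep extremes are scale-bound
reproductions, not re-measurements of the published hardware-scale
screen; the acceptance script reports exactly what the desk-scale sweeps
compute.
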