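# auxmesh

Algorithmic design of auxetic lattices and perfusable tissue-engineering
scaffolds, with an embedded voxel finite-cell mechanics screen.

Auxetic structures have a negative Poisson's ratio ν = −ε_lateral/ε_axial:
they expand laterally when stretched, which makes them ideal conformable
patches for dynamic organs (heart, lung, bladder) and foreshortening-free
stent-like cylinders. Designing them for volumetric (tomographic)
photopolymerization requires generating large families of parametric
lattices and screening their mechanics without hand-meshing each design.
auxmesh implements that workflow for R users:

* **Planar auxetic meshes** — re-entrant honeycomb, arrowhead, sinusoidal
  ligament and pinwheel topologies from design parameters (`n1`, `n2`
  vertical/horizontal element counts, element thickness `t`, offset
  amplitude), as thickness-attributed beam networks.
* **Cylindrical auxetic meshes** — the same families built on the unrolled
  cylinder (parameters `h`, `v`, `t`, radius `R`, height `H`) and mapped
  onto the coat by an arc-length-preserving wrap, seam closed.
* **Organ wrapping** — clip a sheet to a circle, wrap it onto a sphere
  (azimuthal-equidistant), and project it onto an arbitrary closed triangle
  surface by exact closest-point queries; a deterministic synthetic
  heart-like surface is included as a projection target.
* **Perfusable constructs** — hyperbolic-sine channel trees (`n` rosette
  copies, mirrored with a central offset), budding alveoli (mini-sphere
  unions), icosahedral capillary networks (4-way triangle subdivision,
  centroid-to-midpoint beams, thickness gradient, 11-point interpolation,
  wrapping at a 250 µm clearance), boolean carving with inlet/outlet ports
  and flood-fill perfusability checks.
* **Geometry substrate** — capsule signed-distance fields, voxelization,
  SDF boolean CSG, marching-tetrahedra surface extraction, and binary/ASCII
  STL I/O for printing.
* **Finite-cell mechanics** — the lattice is embedded in its voxel grid;
  solid sub-voxels integrate with full stiffness and void sub-voxels with a
  vanishing factor (α = 10⁻⁶), so plane-stress or 3-D linear elasticity
  runs directly on the grid with no meshing. Axial stretch uses prescribed
  top displacement with a roller bottom (free lateral expansion); radial
  stretch expands cylinder end rings. `sweep_poisson` screens whole design
  tables and reports ν per design.

## Worked example

```r
library(auxmesh)

# a 10 x 10 mm re-entrant honeycomb with 6 x 6 elements, 0.2 mm struts
net <- gen_planar_auxetic(planar_design("reentrant", n1 = 6, n2 = 6, t = 0.2))
net
#> beam_network: 72 vertices, 96 beams
#>   thickness: 0.2..0.2 mm; bbox 10 x 10 x 0 mm

# screen its Poisson's ratio: plane-stress finite cells, 1% axial stretch,
# roller bottom
g <- voxelize_network(net, spacing = 0.05, mode = "2d")
r <- solve_elasticity(elastic_problem(g, E = 50, nu_mat = 0.45),
                      stretch_bc("axial", 0.01))
r
#> mech_result (plane_stress_2d, axial stretch): nu = -0.3933
#>   eps_axial 0.01, eps_lateral 0.003933, 23328 dof, residual 1.1e-15
```

ν ≈ −0.39: the mesh widens by about 0.39% for every 1% of stretch —
auxetic. Exporting for printing and building a perfusable construct:

```r
write_stl(extract_surface(voxelize_network(net), 0), "mesh.stl")

tree <- gen_channel_tree(channel_design(d = 1.2, t = 0.9, D = 1.5,
                                        n_copies = 7, amplitude = 0.6,
                                        block = c(10, 10, 12)))
boxed <- assemble_perfusable_construct(list(type = "box", dims = c(10, 10, 12)),
                                       channels = tree, spacing = 0.25)
construct_is_perfusable(boxed, from = c(0, 0, 11.5), to = c(0, 0, 0.5))
#> [1] TRUE
```

A command-line wrapper (`inst/scripts/auxmesh`) exposes the same
operations as subcommands (`generate`, `wrap`, `design`, `simulate`,
`sweep`) with YAML configs and JSON sidecars; see `?aux_main`.

## Voxel container format

`write_voxels`/`read_voxels` persist grids as a minimal little-endian
binary container: magic `"AUXVOX1\n"`, origin (3 × float64), spacing
(float64), shape (3 × int32), then the values in column-major order.

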