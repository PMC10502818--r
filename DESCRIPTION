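Package: auxmesh
Title: Algorithmic Design of Auxetic Lattices and Perfusable Scaffolds
    with a Voxel Finite-Cell Mechanics Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates printable auxetic metamaterial geometry - planar
    meshes (re-entrant honeycomb, arrowhead, sinusoidal ligament, pinwheel),
    cylindrical variants built by arc-length-preserving wrapping, organ-wrapped
    sheets obtained by circle clipping, sphere wrapping and closest-point
    projection, porous foamed matrices, and perfusable constructs (hyperbolic-sine
    channel trees, budding alveoli, icosahedral capillary networks). Lattices are
    represented as thickness-attributed beam networks, rendered to signed-distance
    voxel grids with boolean CSG, and exported as STL triangle surfaces. An
    embedded finite-cell (fictitious-domain) linear-elasticity solver screens
    designs for their Poisson's ratio under axial or radial stretch, enabling
    large parametric sweeps without body-fitted meshing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pracma,
    optparse
Config/testthat/edition: 3
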