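test_that("capsule signed distance matches the point-segment oracle", {
  a <- c(0, 0, 0); b <- c(2, 1, -1); r <- 0.4
  expect_equal(sdf_capsule(a, a, b, r), -r)
  # point at distance r from the midpoint, perpendicular to the axis
  mid <- (a + b) / 2
  ax <- (b - a) / sqrt(sum((b - a)^2))
  perp <- pracma::cross(ax, c(0, 0, 1)); perp <- perp / sqrt(sum(perp^2))
  expect_equal(sdf_capsule(mid + r * perp, a, b, r), 0, tolerance = 1e-12)
  set.seed(42)
  p <- matrix(runif(3000, -3, 4), ncol = 3)
  got <- sdf_capsule(p, a, b, r)
  want <- apply(p, 1, oracle_point_segment, a = a, b = b) - r
  expect_equal(got, want, tolerance = 1e-12)
  # a == b degenerates to a sphere
  expect_equal(sdf_capsule(c(1, 0, 0), a, a, 0.5), 0.5)
})

test_that("voxelized capsule volume approaches the analytic value", {
  L <- 4; t <- 0.8
  net <- beam_network(rbind(c(0, 0, 0), c(L, 0, 0)), rbind(c(1, 2)), t)
  g <- voxelize_network(net, spacing = t / 8)
  vol <- grid_volume(g)
  expect_lt(abs(vol / (pi * t^2 / 4 * L + pi * t^3 / 6) - 1), 0.1)
})

test_that("isolated vertices follow the documented degenerate sphere rule", {
  lone <- beam_network(rbind(c(0, 0, 0)), matrix(integer(0), 0, 2))
  expect_error(voxelize_network(lone, spacing = 0.1), "point_radius")
  g <- voxelize_network(lone, spacing = 0.05, point_radius = 0.4)
  expect_lt(abs(grid_volume(g) / (4 / 3 * pi * 0.4^3) - 1), 0.1)
})

test_that("disjoint beams yield two flood-fill components", {
  net <- beam_network(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 3), c(1, 0, 3)),
                      rbind(c(1, 2), c(3, 4)), 0.4)
  lab <- label_components(grid_indicator(voxelize_network(net, spacing = 0.1)))
  expect_identical(max(lab), 2L)
})

test_that("boolean CSG obeys the signed-distance identities", {
  g <- grid_from_sdf(function(p) sdf_sphere(p, c(0, 0, 0), 1),
                     rep(-1.5, 3), rep(1.5, 3), 0.1)
  expect_identical(sum(grid_indicator(boolean_op(g, g, "subtract"))), 0L)
  empty <- voxel_grid(array(10, dim(g$values)), g$origin, g$spacing)
  expect_equal(boolean_op(g, empty, "union")$values, g$values)
  # union SDF is a pointwise lower bound of both inputs
  g2 <- grid_from_sdf(function(p) sdf_sphere(p, c(0.5, 0, 0), 0.8),
                      rep(-1.5, 3), rep(1.5, 3), 0.1)
  un <- boolean_op(g, g2, "union")
  expect_true(all(un$values <= g$values + 1e-12))
  expect_true(all(un$values <= g2$values + 1e-12))
  expect_error(boolean_op(g, voxel_grid(array(1, c(2, 2, 2))), "union"),
               "share")
})

test_that("cuboid minus centered sphere has the analytic interior volume", {
  box <- 2
  sp <- box / 64
  gb <- grid_from_sdf(function(p) sdf_box(p, rep(-1, 3), rep(1, 3)),
                      rep(-1.2, 3), rep(1.2, 3), sp)
  gs <- grid_from_sdf(function(p) sdf_sphere(p, c(0, 0, 0), 0.6),
                      rep(-1.2, 3), rep(1.2, 3), sp)
  got <- grid_volume(boolean_op(gb, gs, "subtract"))
  want <- box^3 - 4 / 3 * pi * 0.6^3
  expect_lt(abs(got / want - 1), 0.05)
})

test_that("surface extraction is accurate, watertight and oriented", {
  R <- 2
  g <- grid_from_sdf(function(p) sdf_sphere(p, c(0, 0, 0), R),
                     rep(-3, 3), rep(3, 3), R / 32)
  s <- extract_surface(g, 0)
  expect_lt(abs(surface_area(s) / (4 * pi * R^2) - 1), 0.03)
  expect_true(surface_is_watertight(s))
  expect_identical(surface_euler(s), 2L)
  # outward orientation: normals point away from the center
  nrm <- auxmesh:::face_normals(s)
  cen <- (s$vertices[s$faces[, 1], ] + s$vertices[s$faces[, 2], ] +
            s$vertices[s$faces[, 3], ]) / 3
  expect_true(all(rowSums(nrm * cen) > 0))
  # cube
  gc <- grid_from_sdf(function(p) sdf_box(p, rep(-1, 3), rep(1, 3)),
                      rep(-1.5, 3), rep(1.5, 3), 0.1)
  sc <- extract_surface(gc, 0)
  expect_identical(surface_euler(sc), 2L)
  # all-positive grid: empty surface with a warning
  gp <- voxel_grid(array(1, c(4, 4, 4)))
  expect_warning(se <- extract_surface(gp, 0), "empty")
  expect_identical(nrow(se$faces), 0L)
})

test_that("extracted capsule surface stays within one spacing of the truth", {
  net <- beam_network(rbind(c(0, 0, 0), c(3, 0, 0)), rbind(c(1, 2)), 0.8)
  g <- voxelize_network(net, spacing = 0.1)
  s <- extract_surface(g, 0)
  d <- sdf_capsule(s$vertices, c(0, 0, 0), c(3, 0, 0), 0.4)
  expect_lt(max(abs(d)), g$spacing)
})

test_that("voxelization is translation-equivariant", {
  net <- beam_network(rbind(c(0, 0, 0), c(2, 1, 0.5)), rbind(c(1, 2)), 0.5)
  shift <- c(0.7, -1.3, 2.1)
  g1 <- voxelize_network(net, spacing = 0.1)
  g2 <- voxelize_network(transform_network(net, shift = shift), spacing = 0.1)
  expect_equal(g2$origin, g1$origin + shift, tolerance = 1e-9)
  expect_equal(g2$values, g1$values, tolerance = 1e-9)
})

test_that("STL round-trips preserve geometry at float32 precision", {
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                 c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  faces <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
                 c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
                 c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8))
  cube <- tri_surface(verts, faces)
  fb <- tempfile(fileext = ".stl"); fa <- tempfile(fileext = ".stl")
  write_stl(cube, fb, mode = "binary")
  write_stl(cube, fa, mode = "ascii")
  rb <- read_stl(fb); ra <- read_stl(fa)
  expect_identical(nrow(rb$faces), 12L)
  expect_equal(sort(as.vector(rb$vertices)), sort(as.vector(verts)))
  expect_identical(soup_key(rb), soup_key(ra))
  expect_identical(soup_key(rb), soup_key(cube))
})

test_that("malformed STL files raise parse errors", {
  f <- tempfile(fileext = ".stl")
  file.create(f)
  expect_error(read_stl(f), "empty")
  con <- file(f, "wb")
  writeBin(charToRaw(sprintf("%-80s", "binary junk")), con)
  writeBin(1000L, con, size = 4, endian = "little")
  writeBin(as.raw(1:10), con)
  close(con)
  expect_error(read_stl(f), "offset 80")
})

test_that("the voxel container round-trips exactly", {
  g <- grid_from_sdf(function(p) sdf_sphere(p, c(0.3, 0, 0), 1),
                     rep(-1.5, 3), rep(1.5, 3), 0.2)
  f <- tempfile(fileext = ".vox")
  write_voxels(g, f)
  g2 <- read_voxels(f)
  expect_identical(g2$values, g$values)
  expect_identical(g2$origin, g$origin)
  expect_identical(g2$spacing, g$spacing)
})
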