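test_that("the degenerate channel tree is a straight axial channel", {
  net <- gen_channel_tree(channel_design(d = 1, t = 1, D = 0, n_copies = 1,
                                         amplitude = 0, block = c(4, 4, 8)))
  expect_true(all(abs(net$vertices[, 1:2]) < 1e-12))
  expect_equal(range(net$vertices[, 3]), c(0, 8))
  expect_identical(oracle_n_components(net), 1L)
})

test_that("the channel rosette has n-fold symmetry and n disjoint paths", {
  n <- 7
  cd <- channel_design(d = 1, t = 0.6, D = 1.5, n_copies = n, amplitude = 0.6,
                       block = c(10, 10, 12))
  net <- gen_channel_tree(cd)
  th <- 2 * pi / n
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_identical(point_set_key(net$vertices %*% t(rot), 1e-6),
                   point_set_key(net$vertices, 1e-6))
  expect_identical(oracle_n_components(net), 1L)
  # removing the inlet and outlet hubs leaves exactly n disjoint channels
  hubs <- which(abs(net$vertices[, 1]) < 1e-9 & abs(net$vertices[, 2]) < 1e-9 &
                  (abs(net$vertices[, 3] - 12) < 1e-9 | abs(net$vertices[, 3]) < 1e-9))
  expect_identical(length(hubs), 2L)
  keep <- net$beams[!(net$beams[, 1] %in% hubs | net$beams[, 2] %in% hubs), ]
  g <- igraph::graph_from_edgelist(keep, directed = FALSE)
  gs <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  expect_identical(as.integer(igraph::components(gs)$no), as.integer(n))
})

test_that("the channel tree mirrors about the midplane up to the half-pitch twist", {
  n <- 7
  net <- gen_channel_tree(channel_design(d = 1, t = 0.6, D = 1.5, n_copies = n,
                                         amplitude = 0.6, block = c(10, 10, 12)))
  th <- pi / n
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mirrored <- cbind(net$vertices[, 1:2] %*% t(rot[1:2, 1:2]),
                    12 - net$vertices[, 3])
  expect_identical(point_set_key(mirrored, 1e-6),
                   point_set_key(net$vertices, 1e-6))
})

test_that("the alveolus respects its placement contract", {
  a1 <- gen_alveolus(alveolus_design(Rp = 2, r = 1.99 / 2 + 1, n_buds = 1,
                                     spacing = 0.1))
  # n_buds = 1: a single sphere of radius r at the origin
  expect_lt(abs(grid_volume(a1) / (4 / 3 * pi * attr(a1, "radii")[1]^3) - 1),
            0.05)
  al <- gen_alveolus(alveolus_design(Rp = 3, r = 1.2, o = 0.8, n_buds = 9))
  ctr <- attr(al, "centers")
  expect_true(all(sqrt(rowSums(ctr^2)) <= 3 + 1e-9))
  # union volume bounded by the sum of the individual spheres
  expect_lte(grid_volume(al), sum(4 / 3 * pi * attr(al, "radii")^3))
  # random mode is deterministic per seed
  r1 <- gen_alveolus(alveolus_design(Rp = 3, r = 1, o = 0.5, n_buds = 6,
                                     seed = 4, mode = "random"))
  r2 <- gen_alveolus(alveolus_design(Rp = 3, r = 1, o = 0.5, n_buds = 6,
                                     seed = 4, mode = "random"))
  expect_identical(attr(r1, "centers"), attr(r2, "centers"))
  expect_error(gen_alveolus(alveolus_design(Rp = 3, r = 1.2, o = 5,
                                            n_buds = 9)),
               "cannot place")
})

test_that("hollowing leaves a watertight shell of the expected thickness", {
  R <- 2
  g <- grid_from_sdf(function(p) sdf_sphere(p, c(0, 0, 0), R),
                     rep(-2.5, 3), rep(2.5, 3), 0.1)
  sshell <- hollow_shape(g, scale = 0.7)
  expect_gt(sum(sshell$values < 0), 0)
  # shell thickness ~ R (1 - scale), measured by the inner void extent
  void_r <- max(vnorm(grid_centers(sshell)[as.vector(sshell$values >= 0 &
                                                       g$values < 0), ,
                                           drop = FALSE]))
  expect_lt(abs(void_r - 0.7 * R), 2 * g$spacing)
  surf <- extract_surface(sshell, 0)
  expect_true(surface_is_watertight(surf))
  # near-zero scale returns (almost) the original solid
  s0 <- hollow_shape(g, scale = 0.02)
  expect_lte(sum(g$values < 0) - sum(s0$values < 0), 2)
  expect_error(hollow_shape(g, scale = 1), "scale")
})

test_that("icosahedral vessel nets have the exact polyhedral combinatorics", {
  n0 <- gen_icosa_network(vessel_design(level = 0))
  c0 <- attr(n0, "combinatorial")
  expect_identical(nrow(c0$beams), 60L)
  expect_identical(oracle_n_components(c0), 1L)
  deg <- tabulate(as.vector(c0$beams), nrow(c0$vertices))
  expect_identical(sort(unique(deg)), c(2L, 3L))
  expect_identical(sum(deg == 3L), 20L)   # face centroids
  expect_identical(sum(deg == 2L), 30L)   # edge midpoints
  n1 <- gen_icosa_network(vessel_design(level = 1))
  c1 <- attr(n1, "combinatorial")
  expect_identical(nrow(c1$beams), 240L)  # faces quadruple per level
  # every beam carries n_interp - 1 = 10 sub-beams after interpolation
  expect_identical(nrow(n1$beams), 10L * nrow(c1$beams))
  # all interpolated points lie on the circumscribed sphere
  expect_lt(max(abs(vnorm(n1$vertices) - 3)), 1e-9)
})

test_that("vessel wrapping honors the alveolar clearance gap", {
  net <- gen_icosa_network(vessel_design(level = 1, radius = 3))
  al <- gen_alveolus(alveolus_design(Rp = 2.2, r = 1, o = 0.6, n_buds = 7))
  w <- wrap_network_to_offset_surface(net, al, gap = 0.25)
  ctr <- attr(al, "centers"); rad <- attr(al, "radii")
  d <- rep(Inf, nrow(w$vertices))
  for (i in seq_along(rad))
    d <- pmin(d, vnorm(sweep(w$vertices, 2, ctr[i, ])) - rad[i])
  expect_equal(min(d), 0.25, tolerance = 1e-6)
  expect_lt(max(d), 0.25 + 0.15)  # creases may sit slightly proud
  expect_identical(nrow(w$beams), nrow(net$beams))
  # identity when the target sphere is the circumscribed sphere at zero gap
  sph <- gen_alveolus(alveolus_design(Rp = 3.05, r = 3, n_buds = 1,
                                      spacing = 0.2))
  w0 <- wrap_network_to_offset_surface(net, sph, gap = 0)
  expect_lt(max(abs(w0$vertices - net$vertices)), 1e-9)
})

test_that("assembled constructs are perfusable from inlet to outlet", {
  cd <- channel_design(d = 1.2, t = 0.9, D = 1.5, n_copies = 5,
                       amplitude = 0.6, block = c(8, 8, 10))
  net <- gen_channel_tree(cd)
  g <- assemble_perfusable_construct(list(type = "box", dims = c(8, 8, 10)),
                                     channels = net,
                                     cavity = list(type = "sphere",
                                                   center = c(0, 0, 5),
                                                   r = 1.2),
                                     spacing = 0.25)
  ok <- construct_is_perfusable(g, from = c(0, 0, 9.5), to = c(0, 0, 0.5))
  expect_true(as.logical(ok))
  # carving never creates solid: construct solid set is a subset of the box
  box <- grid_from_sdf(function(p) sdf_box(p, c(-4, -4, 0), c(4, 4, 10)),
                       g$origin - g$spacing / 2,
                       g$origin - g$spacing / 2 + dim(g$values) * g$spacing,
                       g$spacing)
  expect_true(all(!(grid_indicator(g) & !grid_indicator(box))))
})

test_that("a channel-free construct has only the cavity and exterior voids", {
  g <- assemble_perfusable_construct(list(type = "box", dims = c(6, 6, 6)),
                                     cavity = list(type = "sphere",
                                                   center = c(0, 0, 3),
                                                   r = 1),
                                     spacing = 0.25)
  lab <- label_components(!grid_indicator(g))
  expect_identical(max(lab), 2L)  # enclosed cavity + exterior
  # a prefabricated sphere of the cavity radius fits inside the cavity
  sph <- grid_from_sdf(function(p) sdf_sphere(p, c(0, 0, 3), 1 - g$spacing),
                       g$origin - g$spacing / 2,
                       g$origin - g$spacing / 2 + dim(g$values) * g$spacing,
                       g$spacing)
  expect_true(all(!grid_indicator(g)[grid_indicator(sph)]))
})

test_that("ports must land on branch points", {
  cd <- channel_design(d = 1.2, t = 0.9, D = 1.5, n_copies = 5,
                       amplitude = 0.6, block = c(8, 8, 10))
  net <- gen_channel_tree(cd)
  expect_error(
    assemble_perfusable_construct(list(type = "box", dims = c(8, 8, 10)),
                                  channels = net,
                                  ports = list(list(x = 3.9, y = 3.9,
                                                    radius = 0.1)),
                                  spacing = 0.25),
    "branch point")
})
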