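test_that("circle clipping keeps, trims and drops beams exactly", {
  net <- gen_planar_auxetic(planar_design("reentrant", n1 = 5, n2 = 5))
  # radius covering the whole mesh: identity
  big <- clip_to_circle(net, center = c(5, 5, 0), radius = 8)
  expect_identical(nrow(big$vertices), nrow(net$vertices))
  expect_identical(nrow(big$beams), nrow(net$beams))
  # all retained vertices inside the circle
  cl <- clip_to_circle(net, center = c(5, 5, 0), radius = 3)
  expect_true(all(sqrt(rowSums(sweep(cl$vertices[, 1:2], 2, c(5, 5))^2))
                  <= 3 + 1e-9))
  # a single crossing beam is trimmed exactly onto the circle
  one <- beam_network(rbind(c(-2, 0.3, 0), c(2, 0.3, 0)), rbind(c(1, 2)), 0.2)
  tr <- clip_to_circle(one, center = c(0, 0, 0), radius = 1)
  rr <- sqrt(rowSums(tr$vertices[, 1:2]^2))
  expect_equal(max(abs(rr - 1)), 0, tolerance = 1e-12)
  expect_error(clip_to_circle(one, center = c(50, 50, 0), radius = 1),
               "nothing remains")
})

test_that("the sphere wrap is azimuthal-equidistant", {
  R <- 5
  center <- beam_network(rbind(c(0, 0, 0), c(0.1, 0, 0)), rbind(c(1, 2)), 0.2)
  w <- wrap_to_sphere(center, R)
  expect_equal(w$vertices[1, ], c(0, 0, R), tolerance = 1e-12)
  # rho = pi R / 2 maps to the equator at exact geodesic distance
  eq <- beam_network(rbind(c(pi * R / 2, 0, 0), c(pi * R / 2, 0.1, 0)),
                     rbind(c(1, 2)), 0.2)
  we <- wrap_to_sphere(eq, R)
  expect_equal(we$vertices[1, ], c(R, 0, 0), tolerance = 1e-9)
  # rho = pi R maps to the antipode
  ap <- beam_network(rbind(c(pi * R, 0, 0), c(pi * R - 0.1, 0, 0)),
                     rbind(c(1, 2)), 0.2)
  wa <- wrap_to_sphere(ap, R)
  expect_equal(wa$vertices[1, ], c(0, 0, -R), tolerance = 1e-9)
  # over-wrap is rejected
  ov <- beam_network(rbind(c(pi * R + 1, 0, 0), c(0, 0, 0)), rbind(c(1, 2)), 0.2)
  expect_error(wrap_to_sphere(ov, R), "antipode")
  # a radial spoke keeps its length as geodesic arc length on the sphere
  spoke <- beam_network(rbind(c(0, 0, 0), c(0.8 * pi * R, 0, 0)),
                        rbind(c(1, 2)), 0.2)
  wsp <- wrap_to_sphere(spoke, R)
  ord <- order(acos(pmin(pmax(wsp$vertices[, 3] / R, -1), 1)))
  v <- wsp$vertices[ord, ] / R
  geo <- sum(R * acos(pmin(pmax(rowSums(v[-nrow(v), ] * v[-1, ]), -1), 1)))
  expect_equal(geo, 0.8 * pi * R, tolerance = 1e-6)
})

test_that("closest-point queries agree with the brute-force oracle", {
  organ <- gen_synthetic_organ(seed = 3, size = 10, spacing = 10 / 16)
  va <- organ$vertices[organ$faces[, 1], , drop = FALSE]
  vb <- organ$vertices[organ$faces[, 2], , drop = FALSE]
  vc <- organ$vertices[organ$faces[, 3], , drop = FALSE]
  # a surface vertex is at distance zero
  expect_equal(closest_point_on_surface(organ$vertices[10, ], organ)$dist, 0)
  # a point offset along a face normal lands on that face
  nrm <- auxmesh:::face_normals(organ)
  cen <- (va + vb + vc) / 3
  p <- cen[5, ] + 0.7 * nrm[5, ]
  got <- closest_point_on_surface(p, organ)
  expect_equal(got$dist, 0.7, tolerance = 1e-9)
  expect_equal(got$point, cen[5, ], tolerance = 1e-9)
  set.seed(11)
  pts <- matrix(runif(1500, -8, 8), ncol = 3)
  got <- closest_point_on_surface(pts, organ)
  want <- vapply(seq_len(nrow(pts)), function(i)
    min(vapply(seq_len(nrow(organ$faces)), function(f)
      oracle_point_triangle(pts[i, ], va[f, ], vb[f, ], vc[f, ]),
      numeric(1))), numeric(1))
  expect_equal(got$dist, want, tolerance = 1e-9)
})

test_that("projection lands on the surface, preserves connectivity and is idempotent", {
  organ <- gen_synthetic_organ(seed = 1, size = 12, spacing = 12 / 24)
  net <- gen_planar_auxetic(planar_design("sinusoidal", 5, 5, width = 8,
                                          height = 8))
  net <- transform_network(net, shift = c(-4, -4, -12))
  pr <- project_network_to_surface(net, organ, subdiv = 2)
  expect_identical(nrow(pr$beams), nrow(subdivide_network(net, 2)$beams))
  expect_identical(max(network_components(pr)), 1L)
  d <- closest_point_on_surface(pr$vertices, organ)$dist
  expect_lt(max(d), 1e-6)
  pr2 <- project_network_to_surface(pr, organ)
  expect_lt(max(abs(pr2$vertices - pr$vertices)), 1e-9)
})

test_that("points outside a sphere project radially onto it", {
  sph <- extract_surface(grid_from_sdf(function(p) sdf_sphere(p, c(0, 0, 0), 1),
                                       rep(-1.4, 3), rep(1.4, 3), 1 / 24), 0)
  net <- beam_network(rbind(c(2, 0, 0), c(0, 2, 0)), rbind(c(1, 2)), 0.1)
  pr <- project_network_to_surface(net, sph)
  rr <- sqrt(rowSums(pr$vertices^2))
  expect_equal(rr, rep(1, nrow(pr$vertices)), tolerance = 5e-3)
  expect_equal(pr$vertices[1, 1], 1, tolerance = 5e-3)
})

test_that("the synthetic organ is a watertight genus-0 deterministic fixture", {
  o1 <- gen_synthetic_organ(seed = 5, size = 12, spacing = 12 / 24)
  o2 <- gen_synthetic_organ(seed = 5, size = 12, spacing = 12 / 24)
  expect_identical(o1$vertices, o2$vertices)
  expect_true(surface_is_watertight(o1))
  expect_identical(surface_euler(o1), 2L)
  o3 <- gen_synthetic_organ(seed = 6, size = 12, spacing = 12 / 24)
  expect_false(isTRUE(all.equal(o1$vertices, o3$vertices)))
})

test_that("the full organ-wrapping pipeline drapes a mesh over the organ", {
  organ <- gen_synthetic_organ(seed = 2, size = 14, spacing = 14 / 28)
  net <- gen_planar_auxetic(planar_design("reentrant", 6, 6, width = 14,
                                          height = 14))
  wrapped <- wrap_to_organ(net, organ, clip_radius = 6, sphere_radius = 7,
                           subdiv = 2)
  d <- closest_point_on_surface(wrapped$vertices, organ)$dist
  expect_lt(max(d), 1e-6)
  # wrapping and projection preserve the clipped sheet's connectivity
  clipped <- clip_to_circle(net, center = c(7, 7, 0), radius = 6)
  expect_identical(max(network_components(wrapped)),
                   max(network_components(clipped)))
})
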