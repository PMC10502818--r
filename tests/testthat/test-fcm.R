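# shared small fixtures: a solid plate grid and a thin re-entrant lattice
plate_grid <- function(spacing = 0.25, w = 10, h = 10)
  grid_from_sdf(function(p) sdf_box(p, c(0, 0, -1), c(w, h, 1)),
                c(0, 0, 0), c(w, h, spacing / 10), spacing)

lattice_grid <- function(t = 0.2, spacing = 0.05) {
  net <- gen_planar_auxetic(planar_design("reentrant", n1 = 4, n2 = 4, t = t))
  voxelize_network(net, spacing = spacing, mode = "2d")
}

test_that("a homogeneous plate returns the material Poisson ratio", {
  p <- elastic_problem(plate_grid(), E = 50, nu_mat = 0.3)
  r <- solve_elasticity(p, stretch_bc("axial", 0.01))
  expect_lt(abs(r$nu / 0.3 - 1), 0.01)
  expect_equal(r$eps_axial, 0.01, tolerance = 1e-9)
  expect_identical(poisson_ratio(r), r$nu)
})

test_that("poisson_ratio implements the strain-ratio convention", {
  expect_equal(poisson_ratio(list(eps_axial = 0.10, eps_lateral = 0.05)), -0.5)
  expect_equal(poisson_ratio(list(eps_axial = 0.10, eps_lateral = 0)), 0)
  expect_error(poisson_ratio(list(eps_axial = 0, eps_lateral = 0.1)), "zero")
})

test_that("a least-squares lateral-strain fit agrees with the band estimator", {
  p <- elastic_problem(plate_grid(), E = 50, nu_mat = 0.3)
  r <- solve_elasticity(p, stretch_bc("axial", 0.01))
  sel <- r$solid_nodes
  fit <- stats::lm.fit(cbind(1, r$nodes[sel, 1]), r$u[sel, 1])
  eps_fit <- fit$coefficients[2]
  expect_lt(abs(eps_fit / r$eps_lateral - 1), 0.05)
})

test_that("the cantilever tip deflection matches Euler-Bernoulli", {
  g <- grid_from_sdf(function(p) sdf_box(p, c(0, 0, -1), c(16, 2, 1)),
                     c(0, 0, 0), c(16, 2, 0.005), 0.05)
  cb <- solve_cantilever(elastic_problem(g, E = 50, nu_mat = 0.3), load = 0.01)
  expect_lt(abs(cb$tip_deflection / cb$euler_bernoulli - 1), 0.05)
})

test_that("thin re-entrant lattices expand laterally when stretched", {
  r <- solve_elasticity(elastic_problem(lattice_grid(), E = 50, nu_mat = 0.45),
                        stretch_bc("axial", 0.01))
  expect_lt(r$nu, 0)
  expect_gt(r$eps_lateral, 0)
})

test_that("results are insensitive to the void stiffness factor", {
  for (g in list(plate_grid(), lattice_grid())) {
    n6 <- solve_elasticity(elastic_problem(g, alpha_void = 1e-6),
                           stretch_bc("axial", 0.01))$nu
    n8 <- solve_elasticity(elastic_problem(g, alpha_void = 1e-8),
                           stretch_bc("axial", 0.01))$nu
    expect_lt(abs(n6 - n8) / max(abs(n6), 1e-12), 0.01)
  }
})

test_that("the plate solution is grid-converged", {
  n1 <- solve_elasticity(elastic_problem(plate_grid(spacing = 0.5)),
                         stretch_bc("axial", 0.01))$nu
  n2 <- solve_elasticity(elastic_problem(plate_grid(spacing = 0.25)),
                         stretch_bc("axial", 0.01))$nu
  expect_lt(abs(n2 - n1) / abs(n1), 0.005)
})

test_that("the solver is linear in the applied strain", {
  p <- elastic_problem(lattice_grid(), E = 50, nu_mat = 0.45)
  r1 <- solve_elasticity(p, stretch_bc("axial", 0.01))
  r2 <- solve_elasticity(p, stretch_bc("axial", 0.02))
  expect_equal(r2$u, 2 * r1$u, tolerance = 1e-9)
  expect_equal(r2$nu, r1$nu, tolerance = 1e-9)
})

test_that("reaction forces balance between the loaded and constrained edges", {
  p <- elastic_problem(plate_grid(), E = 50, nu_mat = 0.3)
  r <- solve_elasticity(p, stretch_bc("axial", 0.01))
  expect_lt(abs(r$reaction_loaded + r$reaction_constrained) /
              abs(r$reaction_loaded), 1e-8)
})

test_that("fixed-bottom constraint lowers the apparent lateral expansion", {
  g <- lattice_grid()
  roll <- solve_elasticity(elastic_problem(g), stretch_bc("axial", 0.01))
  fix <- solve_elasticity(elastic_problem(g),
                          stretch_bc("axial", 0.01,
                                     constraint = "fixed_bottom"))
  expect_lt(abs(fix$nu), abs(roll$nu) + 1e-9)
})

test_that("3-D solid cylinders recover the material response axially", {
  g <- grid_from_sdf(function(p) sdf_cylinder(p, c(0, 0, 1.5), 1, 3),
                     c(-1.3, -1.3, -0.2), c(1.3, 1.3, 3.2), 0.1)
  r <- solve_elasticity(elastic_problem(g, E = 50, nu_mat = 0.3),
                        stretch_bc("axial", 0.01))
  expect_lt(abs(r$nu / 0.3 - 1), 0.02)
})

test_that("sweeps are deterministic and capture failures per row", {
  designs <- data.frame(n1 = c(3, 3, 2), n2 = c(3, 3, 2), t = c(0.3, 0.3, 0.3))
  sw <- sweep_poisson(designs,
                      geometry = function(row)
                        gen_planar_auxetic(planar_design("reentrant",
                                                         n1 = row$n1,
                                                         n2 = row$n2,
                                                         t = row$t)),
                      bc = stretch_bc("axial", 0.01),
                      spacing = 0.1, mode = "2d")
  expect_identical(sw$nu[1], sw$nu[2])  # duplicate rows are bit-identical
  expect_true(all(sw$status == "ok"))
  expect_false(anyNA(sw$nu))
  # a failing row is recorded, not fatal
  bad <- data.frame(n1 = 3, n2 = 3, t = 0.3)
  sw2 <- sweep_poisson(bad,
                       geometry = function(row) stop("boom"),
                       bc = stretch_bc("axial", 0.01), spacing = 0.1,
                       mode = "2d")
  expect_true(is.na(sw2$nu[1]))
  expect_match(sw2$status[1], "boom")
})
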