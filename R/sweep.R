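#' Sweep Poisson's ratios over a design table
#'
#' Runs the finite-cell stretch screen once per design row: generate the
#' lattice, render it on the voxel grid, check that the solid connects the
#' two loaded boundaries, solve, and extract the Poisson's ratio. Failures
#' (under-resolved or disconnected designs, solver errors) are recorded
#' per row in the `status` column rather than aborting the sweep; their `nu`
#' is `NA`. The sweep is deterministic given the design table and solver
#' settings.
#'
#' @param designs data.frame of design parameters, one row per design.
#' @param geometry function taking one design row (as a list) and returning
#'   a [beam_network()].
#' @param bc a [stretch_bc()].
#' @param spacing voxel size (mm).
#' @param mode `"2d"` (plane stress; planar meshes) or `"3d"`.
#' @param E,nu_mat,alpha_void,quadrature_depth material/solver settings, see
#'   [elastic_problem()].
#' @param padding grid margin (mm) passed to [voxelize_network()].
#' @param verbose print one line per design.
#' @return the design table with columns `nu` and `status` appended, plus
#'   attributes `nu_min` and `nu_max` (over successful rows); class
#'   `sweep_result`.
#' @export
sweep_poisson <- function(designs, geometry, bc, spacing, mode = c("2d", "3d"),
                          E = 50, nu_mat = 0.45, alpha_void = 1e-6,
                          quadrature_depth = 2L, padding = NULL,
                          verbose = FALSE) {
  mode <- match.arg(mode)
  nu <- rep(NA_real_, nrow(designs))
  status <- character(nrow(designs))
  for (i in seq_len(nrow(designs))) {
    row <- as.list(designs[i, , drop = FALSE])
    res <- tryCatch({
      net <- geometry(row)
      g <- suppressWarnings(
        voxelize_network(net, spacing = spacing, padding = padding,
                         mode = if (mode == "2d") "2d" else "3d"))
      check_load_path(g, axial_col = if (mode == "2d") 2L else 3L)
      p <- elastic_problem(g, E = E, nu_mat = nu_mat, alpha_void = alpha_void,
                           quadrature_depth = quadrature_depth)
      solve_elasticity(p, bc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- conditionMessage(res)
    } else {
      nu[i] <- res$nu
      status[i] <- "ok"
    }
    if (verbose)
      cat(sprintf("[%3d/%3d] %s nu = %s\n", i, nrow(designs),
                  paste(names(designs), unlist(designs[i, ]), sep = "=",
                        collapse = " "),
                  if (is.na(nu[i])) status[i] else sprintf("%.3f", nu[i])))
  }
  out <- cbind(designs, nu = nu, status = status)
  ok <- !is.na(nu)
  attr(out, "nu_min") <- if (any(ok)) min(nu[ok]) else NA_real_
  attr(out, "nu_max") <- if (any(ok)) max(nu[ok]) else NA_real_
  class(out) <- c("sweep_result", class(out))
  out
}

# error early (with a clear message) when the solid does not connect the two
# loaded boundaries of the grid
check_load_path <- function(g, axial_col) {
  ind <- grid_indicator(g)
  lab <- label_components(ind)
  sh <- dim(lab)
  ax <- apply(lab, axial_col, function(s) unique(s[s > 0L]))
  occ <- which(vapply(seq_len(sh[axial_col]), function(k) {
    sl <- if (axial_col == 2L) lab[, k, ] else lab[, , k]
    any(sl > 0L)
  }, logical(1)))
  lo <- occ[1]; hi <- occ[length(occ)]
  slab <- function(k) {
    sl <- if (axial_col == 2L) lab[, k, ] else lab[, , k]
    unique(sl[sl > 0L])
  }
  if (!length(intersect(slab(lo), slab(hi))))
    stopf("disconnected load path: no solid component spans the stretch axis")
  invisible(TRUE)
}

#' Planar re-entrant design sweep
#'
#' The scaled-down reproduction of the planar re-entrant honeycomb screen:
#' all combinations of `n1`, `n2` and `t` on a `width` x `height` mesh,
#' plane-stress finite cells, 1% axial stretch with roller bottom.
#'
#' @param n1,n2 integer vectors of element counts.
#' @param t numeric vector of element thicknesses (mm).
#' @param width,height mesh extents (mm).
#' @param spacing voxel size (mm).
#' @param strain applied axial strain.
#' @param ... passed to [sweep_poisson()].
#' @return a `sweep_result` (see [sweep_poisson()]).
#' @export
sweep_planar_reentrant <- function(n1 = c(2, 4, 6, 8), n2 = c(2, 4, 6, 8),
                                   t = c(0.1, 0.2, 0.3, 0.4, 0.5),
                                   width = 10, height = 10, spacing = 0.04,
                                   strain = 0.01, ...) {
  designs <- expand.grid(n1 = n1, n2 = n2, t = t)
  sweep_poisson(designs,
                geometry = function(row)
                  gen_planar_auxetic(planar_design("reentrant", n1 = row$n1,
                                                   n2 = row$n2, t = row$t,
                                                   width = width,
                                                   height = height)),
                bc = stretch_bc("axial", strain),
                spacing = spacing, mode = "2d", ...)
}

#' Cylindrical design sweeps
#'
#' Axial-stretch screen over the four cylinder topologies (and a
#' radial-stretch screen over the horizontally oriented re-entrant
#' honeycomb cylinders), swept over `h`, `v` and `t`.
#'
#' @param kinds cylinder topologies to include.
#' @param h,v,t design parameter vectors (see [cylinder_design()]).
#' @param R,H cylinder radius and height (mm).
#' @param spacing voxel size (mm).
#' @param strain applied strain.
#' @param ... passed to [sweep_poisson()].
#' @return a `sweep_result`.
#' @export
sweep_cylinder_axial <- function(kinds = c("reentrant_vertical",
                                           "reentrant_horizontal",
                                           "sinusoidal", "pinwheel"),
                                 h = c(3, 5), v = c(8, 12),
                                 t = c(0.2, 0.35),
                                 R = 1.25, H = 3.75, spacing = 0.08,
                                 strain = 0.01, ...) {
  designs <- expand.grid(kind = kinds, h = h, v = v, t = t,
                         stringsAsFactors = FALSE)
  sweep_poisson(designs,
                geometry = function(row)
                  gen_cylindrical_auxetic(cylinder_design(row$kind, R = R,
                                                          H = H, h = row$h,
                                                          v = row$v, t = row$t)),
                bc = stretch_bc("axial", strain),
                spacing = spacing, mode = "3d", ...)
}

#' @rdname sweep_cylinder_axial
#' @export
sweep_cylinder_radial <- function(h = c(3, 5), v = c(8, 12),
                                  t = c(0.2, 0.3, 0.45),
                                  R = 1.25, H = 3.75, spacing = 0.08,
                                  strain = 0.01, ...) {
  designs <- expand.grid(kind = "reentrant_horizontal", h = h, v = v, t = t,
                         stringsAsFactors = FALSE)
  sweep_poisson(designs,
                geometry = function(row)
                  gen_cylindrical_auxetic(cylinder_design(row$kind, R = R,
                                                          H = H, h = row$h,
                                                          v = row$v, t = row$t)),
                bc = stretch_bc("radial", strain),
                spacing = spacing, mode = "3d", ...)
}
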