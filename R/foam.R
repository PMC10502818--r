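#' Generate a porous matrix by a foaming algorithm
#'
#' Carves randomly placed spherical pores out of a solid box until the void
#' fraction reaches the target porosity (within a tolerance of 0.02 by voxel
#' counting). Pores may overlap each other but are kept clear of a
#' one-voxel boundary shell so the carved solid stays watertight.
#' Deterministic for a fixed seed.
#'
#' @param dims box dimensions (mm), length 3.
#' @param porosity target void fraction in `[0, 1)`.
#' @param pore_radius length-2 `(min, max)` pore radius (mm).
#' @param seed integer RNG seed.
#' @param spacing voxel size (mm); default `min(pore_radius) / 4`.
#' @param tol acceptable deviation of the achieved void fraction.
#' @param max_iter give up (with an error) after this many pores.
#' @return a [voxel_grid()] of signed distances with attributes
#'   `pore_centers` (k x 3 matrix) and `pore_radii`.
#' @export
gen_foam <- function(dims, porosity, pore_radius, seed,
                     spacing = NULL, tol = 0.02, max_iter = 10000L) {
  dims <- as.numeric(dims)
  if (porosity < 0 || porosity >= 1) stopf("porosity must be in [0, 1)")
  pore_radius <- sort(as.numeric(pore_radius))
  if (any(pore_radius <= 0)) stopf("pore radii must be > 0")
  if (is.null(spacing)) spacing <- pore_radius[1] / 4
  g <- grid_from_sdf(function(p) sdf_box(p, c(0, 0, 0), dims),
                     c(0, 0, 0) - 2 * spacing, dims + 2 * spacing, spacing)
  box_solid <- sum(g$values < 0)
  if (porosity == 0) {
    attr(g, "pore_centers") <- matrix(numeric(0), 0, 3)
    attr(g, "pore_radii") <- numeric(0)
    return(g)
  }
  shell <- spacing  # pores stay this clear of the box boundary
  centers <- list(); radii <- numeric(0)
  with_seed(seed, {
    it <- 0L
    repeat {
      void <- 1 - sum(g$values < 0) / box_solid
      if (void >= porosity - tol) break
      it <- it + 1L
      if (it > max_iter)
        stopf("gen_foam: porosity %.2f unreachable after %d pores (achieved %.3f)",
              porosity, max_iter, void)
      r <- runif(1, pore_radius[1], pore_radius[2])
      lim <- r + shell
      if (any(dims <= 2 * lim))
        stopf("gen_foam: pore radius %.3g does not fit the box", r)
      ctr <- runif(3, lim, dims - lim)
      cand <- voxel_grid(array(pmax(g$values,
                                    -sdf_sphere(grid_centers(g), ctr, r)),
                               dim(g$values)), g$origin, g$spacing)
      void_after <- 1 - sum(cand$values < 0) / box_solid
      if (void_after > porosity + tol) next  # pore too large for the remaining budget
      g <- cand
      centers[[length(centers) + 1L]] <- ctr
      radii <- c(radii, r)
    }
  })
  achieved <- 1 - sum(g$values < 0) / box_solid
  if (abs(achieved - porosity) > tol && achieved < porosity)
    stopf("gen_foam: achieved void fraction %.3f misses target %.2f", achieved, porosity)
  attr(g, "pore_centers") <- do.call(rbind, centers)
  attr(g, "pore_radii") <- radii
  g
}
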