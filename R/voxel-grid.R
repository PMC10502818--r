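#' Regular voxel grid
#'
#' Axis-aligned isotropic scalar grid. `values[i, j, k]` is sampled at the
#' voxel *center* `origin + (c(i, j, k) - 1) * spacing`. Values are either a
#' signed distance in mm (negative inside the solid, the package-wide
#' convention) or an inside/outside indicator.
#'
#' @param values 3-D numeric array (use a third extent of 1 for planar grids).
#' @param origin coordinates (mm) of the center of voxel `[1, 1, 1]`.
#' @param spacing isotropic voxel edge length (mm), `> 0`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, origin = c(0, 0, 0), spacing = 1) {
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) stopf("values must be a 3-D array")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stopf("spacing must be a single positive number")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %s voxels @ %.4g mm, origin (%s)\n",
              paste(dim(x$values), collapse = " x "), x$spacing,
              paste(sprintf("%.3g", x$origin), collapse = ", ")))
  cat(sprintf("  values in [%.3g, %.3g]; %d interior voxels\n",
              min(x$values), max(x$values), sum(x$values < 0)))
  invisible(x)
}

# voxel-center coordinate axes
grid_axes <- function(g) {
  sh <- dim(g$values)
  lapply(1:3, function(k) g$origin[k] + (seq_len(sh[k]) - 1) * g$spacing)
}

#' Voxel-center coordinates
#'
#' All voxel centers as an N x 3 matrix in storage order (x fastest).
#' @param g a [voxel_grid()].
#' @export
grid_centers <- function(g) {
  ax <- grid_axes(g); sh <- dim(g$values)
  cbind(rep(ax[[1]], times = sh[2] * sh[3]),
        rep(rep(ax[[2]], each = sh[1]), times = sh[3]),
        rep(ax[[3]], each = sh[1] * sh[2]))
}

#' Inside/outside indicator of a voxel grid
#'
#' Thresholds the stored values at `iso`: a voxel is solid iff its center
#' value is below `iso` (for signed distances, strictly inside).
#' @param g a [voxel_grid()].
#' @param iso threshold (default 0).
#' @return logical array of the grid's shape.
#' @export
grid_indicator <- function(g, iso = 0) g$values < iso

#' Solid volume of a voxel grid (mm^3, voxel-counting)
#' @param g a [voxel_grid()].
#' @param iso threshold passed to [grid_indicator()].
#' @export
grid_volume <- function(g, iso = 0) sum(grid_indicator(g, iso)) * g$spacing^3

#' Signed distance to a capsule
#'
#' Exact Euclidean signed distance from points `p` to the capsule obtained by
#' inflating segment `ab` by radius `r` (negative inside). When `a == b` the
#' capsule degenerates to a sphere of radius `r`; this is allowed and is how
#' isolated lattice vertices are rendered.
#'
#' @param p query points, n x 3 matrix (or length-3 vector).
#' @param a,b segment endpoints (mm).
#' @param r capsule radius (mm), `> 0`.
#' @return numeric vector of signed distances (mm).
#' @export
sdf_capsule <- function(p, a, b, r) {
  if (r <= 0) stopf("capsule radius must be > 0")
  p <- as_points(p)
  a <- as.numeric(a); b <- as.numeric(b)
  ba <- b - a
  bb <- sum(ba * ba)
  pa <- sweep(p, 2, a)
  h <- if (bb < 1e-300) rep(0, nrow(p)) else clamp(drop(pa %*% ba) / bb, 0, 1)
  d <- pa - outer(h, ba)
  sqrt(rowSums(d * d)) - r
}

#' Signed distance to a sphere
#' @param p query points, n x 3 matrix.
#' @param center sphere center (mm).
#' @param r radius (mm).
#' @export
sdf_sphere <- function(p, center, r) {
  p <- as_points(p)
  vnorm(sweep(p, 2, as.numeric(center))) - r
}

#' Signed distance to an axis-aligned box
#' @param p query points, n x 3 matrix.
#' @param lower,upper box corners (mm).
#' @export
sdf_box <- function(p, lower, upper) {
  p <- as_points(p)
  c0 <- (as.numeric(lower) + as.numeric(upper)) / 2
  hw <- (as.numeric(upper) - as.numeric(lower)) / 2
  q <- abs(sweep(p, 2, c0)) - matrix(hw, nrow(p), 3, byrow = TRUE)
  qp <- pmax(q, 0)
  sqrt(rowSums(qp * qp)) + pmin(apply(q, 1, max), 0)
}

#' Signed distance to a z-aligned finite cylinder
#' @param p query points, n x 3 matrix.
#' @param center cylinder center (mm).
#' @param r radius (mm).
#' @param h full height along z (mm).
#' @export
sdf_cylinder <- function(p, center, r, h) {
  p <- sweep(as_points(p), 2, as.numeric(center))
  dr <- sqrt(p[, 1]^2 + p[, 2]^2) - r
  dz <- abs(p[, 3]) - h / 2
  drp <- pmax(dr, 0); dzp <- pmax(dz, 0)
  sqrt(drp^2 + dzp^2) + pmin(pmax(dr, dz), 0)
}

#' Sample a signed-distance function onto a voxel grid
#'
#' @param fn function taking an n x 3 point matrix, returning n distances.
#' @param lower,upper bounds (mm) of the region to cover.
#' @param spacing voxel size (mm).
#' @return a [voxel_grid()].
#' @export
grid_from_sdf <- function(fn, lower, upper, spacing) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  sh <- pmax(1L, as.integer(ceiling((upper - lower) / spacing)))
  origin <- lower + spacing / 2
  g <- voxel_grid(array(0, sh), origin, spacing)
  g$values <- array(fn(grid_centers(g)), sh)
  g
}

#' Render a beam network as a signed-distance voxel grid
#'
#' The grid covers the network bounding box (inflated by half the maximum
#' thickness) plus `padding` on every side. Each beam contributes the exact
#' capsule signed distance of its segment inflated by `thickness / 2`; the
#' grid stores the union (pointwise minimum). Vertices not referenced by any
#' beam are rendered as spheres of radius `point_radius` (degenerate rule).
#'
#' With `mode = "2d"` the network is treated as planar art-work: the z
#' coordinate is ignored and beams become 2-D stadium shapes on a grid of
#' shape `(nx, ny, 1)`; this is the substrate for the plane-stress
#' finite-cell screen.
#'
#' @param net a [beam_network()].
#' @param spacing voxel size (mm); default `min(thickness) / 6`.
#' @param padding extra margin (mm) beyond the inflated bounding box;
#'   default `max(thickness)`.
#' @param mode `"3d"` (default) or `"2d"`.
#' @param point_radius sphere radius (mm) for isolated vertices; default
#'   `max(thickness) / 2` when the network has beams, otherwise required.
#' @param grid optional existing [voxel_grid()]: the network is rendered onto
#'   that grid's exact lattice (origin/spacing/shape) instead of a fresh
#'   bounding-box grid, so the result can be combined with [boolean_op()].
#' @return a [voxel_grid()] of signed distances (mm).
#' @export
voxelize_network <- function(net, spacing = NULL, padding = NULL,
                             mode = c("3d", "2d"), point_radius = NULL,
                             grid = NULL) {
  mode <- match.arg(mode)
  if (!nrow(net$vertices)) stopf("cannot voxelize an empty network")
  has_beams <- nrow(net$beams) > 0
  if (!has_beams && is.null(point_radius))
    stopf("network has no beams: supply point_radius to render vertices as spheres")
  tmax <- if (has_beams) max(net$thickness) else 2 * point_radius
  tmin <- if (has_beams) min(net$thickness) else 2 * point_radius
  if (is.null(point_radius)) point_radius <- tmax / 2
  if (is.null(spacing)) spacing <- if (is.null(grid)) tmin / 6 else grid$spacing
  if (is.null(padding)) padding <- tmax
  if (spacing > tmin / 2)
    warnf("spacing %.3g mm under-resolves the thinnest beam (%.3g mm)", spacing, tmin)

  if (is.null(grid)) {
    bb <- network_bbox(net, inflate = tmax / 2 + padding)
    if (mode == "2d") { bb[1, 3] <- 0; bb[2, 3] <- 0 }
    sh <- pmax(1L, as.integer(ceiling((bb[2, ] - bb[1, ]) / spacing)))
    if (mode == "2d") sh[3] <- 1L
    origin <- bb[1, ] + spacing / 2
    far <- sum(bb[2, ] - bb[1, ]) + tmax + 1
  } else {
    spacing <- grid$spacing
    sh <- dim(grid$values)
    origin <- grid$origin
    far <- sum(sh * spacing) + tmax + 1
  }
  vals <- array(far, sh)
  ax <- list(origin[1] + (seq_len(sh[1]) - 1) * spacing,
             origin[2] + (seq_len(sh[2]) - 1) * spacing,
             origin[3] + (seq_len(sh[3]) - 1) * spacing)

  flat <- function(q) if (mode == "2d") cbind(q[, 1:2], 0) else q
  paint <- function(a, b, r) {
    lo <- pmin(a, b) - r - 2 * spacing
    hi <- pmax(a, b) + r + 2 * spacing
    ir <- lapply(1:3, function(k) which(ax[[k]] >= lo[k] & ax[[k]] <= hi[k]))
    if (any(!lengths(ir))) return()
    pts <- cbind(rep(ax[[1]][ir[[1]]], times = length(ir[[2]]) * length(ir[[3]])),
                 rep(rep(ax[[2]][ir[[2]]], each = length(ir[[1]])),
                     times = length(ir[[3]])),
                 rep(ax[[3]][ir[[3]]], each = length(ir[[1]]) * length(ir[[2]])))
    d <- sdf_capsule(pts, a, b, r)
    sub <- vals[ir[[1]], ir[[2]], ir[[3]]]
    vals[ir[[1]], ir[[2]], ir[[3]]] <<- pmin(sub, array(d, dim(sub)))
  }

  for (i in seq_len(nrow(net$beams))) {
    a <- flat(net$vertices)[net$beams[i, 1], ]
    b <- flat(net$vertices)[net$beams[i, 2], ]
    paint(a, b, net$thickness[i] / 2)
  }
  lone <- setdiff(seq_len(nrow(net$vertices)), unique(as.vector(net$beams)))
  for (i in lone) {
    a <- flat(net$vertices)[i, ]
    paint(a, a, point_radius)
  }
  voxel_grid(vals, origin, spacing)
}

#' Boolean CSG on voxel grids
#'
#' Signed-distance combination of two grids sampled on the identical lattice:
#' `union = min(A, B)`, `subtract = max(A, -B)`, `intersect = max(A, B)`.
#' (The result is an exact SDF only away from the cut loci, as usual for
#' distance-field CSG; the zero level set is exact.)
#'
#' @param gA,gB [voxel_grid()]s sharing origin, spacing and shape.
#' @param op one of `"union"`, `"subtract"`, `"intersect"`.
#' @return a [voxel_grid()].
#' @export
boolean_op <- function(gA, gB, op = c("union", "subtract", "intersect")) {
  op <- match.arg(op)
  if (!isTRUE(all.equal(dim(gA$values), dim(gB$values))) ||
      max(abs(gA$origin - gB$origin)) > 1e-9 ||
      abs(gA$spacing - gB$spacing) > 1e-12)
    stopf("boolean_op: grids must share origin, spacing and shape")
  v <- switch(op,
              union     = pmin(gA$values, gB$values),
              subtract  = pmax(gA$values, -gB$values),
              intersect = pmax(gA$values, gB$values))
  voxel_grid(array(v, dim(gA$values)), gA$origin, gA$spacing)
}

#' Connected components of a voxel indicator (6-connectivity)
#'
#' Frontier-vectorized flood fill over face-adjacent voxels.
#' @param ind logical array (2-D arrays are treated as one-voxel-thick 3-D).
#' @return integer array of the same shape: 0 for background, component ids
#'   1..k for foreground voxels.
#' @export
label_components <- function(ind) {
  if (length(dim(ind)) == 2L) dim(ind) <- c(dim(ind), 1L)
  sh <- dim(ind)
  nx <- sh[1]; ny <- sh[2]; nz <- sh[3]; nxy <- nx * ny
  labels <- integer(length(ind))
  ind_v <- as.vector(ind)
  neighbors <- function(idx) {
    i0 <- idx - 1L
    ix <- i0 %% nx; iy <- (i0 %/% nx) %% ny; iz <- i0 %/% nxy
    c(idx[ix > 0L] - 1L, idx[ix < nx - 1L] + 1L,
      idx[iy > 0L] - nx, idx[iy < ny - 1L] + nx,
      idx[iz > 0L] - nxy, idx[iz < nz - 1L] + nxy)
  }
  comp <- 0L
  todo <- which(ind_v)
  seen <- logical(length(ind))
  for (seed in todo) {
    if (seen[seed]) next
    comp <- comp + 1L
    frontier <- seed
    seen[seed] <- TRUE
    labels[seed] <- comp
    while (length(frontier)) {
      nb <- unique(neighbors(frontier))
      nb <- nb[ind_v[nb] & !seen[nb]]
      seen[nb] <- TRUE
      labels[nb] <- comp
      frontier <- nb
    }
  }
  array(labels, sh)
}

#' Write / read the package's voxel container
#'
#' A minimal self-describing binary container (documented in the README):
#' magic `"AUXVOX1\n"` (8 bytes), origin (3 doubles), spacing (1 double),
#' shape (3 int32), then `prod(shape)` doubles in column-major order, all
#' little-endian.
#'
#' @param g a [voxel_grid()].
#' @param path file path.
#' @return `write_voxels` returns `path` invisibly; `read_voxels` returns a
#'   [voxel_grid()].
#' @export
write_voxels <- function(g, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("AUXVOX1\n"), con)
  writeBin(as.numeric(c(g$origin, g$spacing)), con, size = 8, endian = "little")
  writeBin(as.integer(dim(g$values)), con, size = 4, endian = "little")
  writeBin(as.numeric(g$values), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_voxels
#' @export
read_voxels <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(rawToChar(magic), "AUXVOX1\n"))
    stopf("%s: not an AUXVOX container (bad magic at byte 0)", path)
  hd <- readBin(con, "numeric", 4, size = 8, endian = "little")
  sh <- readBin(con, "integer", 3, size = 4, endian = "little")
  n <- prod(sh)
  vals <- readBin(con, "numeric", n, size = 8, endian = "little")
  if (length(vals) != n)
    stopf("%s: truncated voxel payload (expected %d values, got %d)",
          path, n, length(vals))
  voxel_grid(array(vals, sh), hd[1:3], hd[4])
}
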