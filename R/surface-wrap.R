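#' Clip a planar beam network to a circle
#'
#' Vertices outside the circle are dropped; beams crossing the boundary are
#' trimmed at the exact segment-circle intersection (new boundary vertices
#' are inserted on the circle). Beams whose chord passes through the circle
#' with both endpoints outside keep their interior chord segment.
#'
#' @param net a planar [beam_network()] (z = 0).
#' @param center circle center (mm); only x and y are used.
#' @param radius circle radius (mm), `> 0`.
#' @return the clipped [beam_network()].
#' @export
clip_to_circle <- function(net, center = c(0, 0, 0), radius) {
  if (radius <= 0) stopf("radius must be > 0")
  ctr <- as.numeric(center)[1:2]
  v2 <- sweep(net$vertices[, 1:2, drop = FALSE], 2, ctr)
  r2 <- rowSums(v2 * v2)
  inside <- r2 <= radius^2 + 1e-12
  pieces <- list(); th <- numeric(0)
  for (i in seq_len(nrow(net$beams))) {
    a <- net$vertices[net$beams[i, 1], ]
    b <- net$vertices[net$beams[i, 2], ]
    ina <- inside[net$beams[i, 1]]; inb <- inside[net$beams[i, 2]]
    d <- (b - a)[1:2]; f <- (a[1:2] - ctr)
    qa <- sum(d * d); qb <- 2 * sum(f * d); qc <- sum(f * f) - radius^2
    disc <- qb^2 - 4 * qa * qc
    ts <- if (disc > 0 && qa > 0) sort((-qb + c(-1, 1) * sqrt(disc)) / (2 * qa))
          else numeric(0)
    seg <- NULL
    if (ina && inb) {
      seg <- rbind(a, b)
    } else if (ina && !inb) {
      t1 <- ts[ts > -1e-12 & ts < 1 + 1e-12][1]
      if (!is.na(t1)) seg <- rbind(a, a + t1 * (b - a))
    } else if (!ina && inb) {
      t1 <- rev(ts[ts > -1e-12 & ts < 1 + 1e-12])[1]
      if (!is.na(t1)) seg <- rbind(a + t1 * (b - a), b)
    } else if (length(ts) == 2 && ts[1] > 1e-9 && ts[2] < 1 - 1e-9) {
      seg <- rbind(a + ts[1] * (b - a), a + ts[2] * (b - a))
    }
    if (!is.null(seg) && sum((seg[2, ] - seg[1, ])^2) > 1e-18) {
      pieces[[length(pieces) + 1L]] <- seg
      th <- c(th, net$thickness[i])
    }
  }
  if (!length(pieces)) stopf("clip_to_circle: nothing remains inside radius %.3g", radius)
  nets <- lapply(seq_along(pieces), function(k) {
    beam_network(pieces[[k]], cbind(1L, 2L), th[k])
  })
  merge_networks(nets, tol = 1e-9)
}

#' Wrap a circular planar mesh onto a sphere
#'
#' Azimuthal-equidistant mapping: a planar point at polar coordinates
#' `(rho, phi)` about the origin maps to the sphere point at polar angle
#' `psi = rho / R` and azimuth `phi`, i.e.
#' `(R sin(psi) cos(phi), R sin(psi) sin(phi), R cos(psi))`. Geodesic
#' distance from the pole equals the planar radial distance exactly, which
#' keeps the auxetic cells nearly undistorted. Beams are subdivided (5
#' degrees of polar angle per segment) before mapping so they follow the
#' sphere.
#'
#' @param net a planar [beam_network()] centered at the origin (e.g. from
#'   [clip_to_circle()]).
#' @param R sphere radius (mm).
#' @param max_angle subdivision resolution (radians of arc per segment).
#' @return a [beam_network()] on the sphere of radius `R`.
#' @export
wrap_to_sphere <- function(net, R, max_angle = 5 * pi / 180) {
  if (R <= 0) stopf("R must be > 0")
  rho <- sqrt(rowSums(net$vertices[, 1:2, drop = FALSE]^2))
  if (any(rho > pi * R + 1e-9))
    stopf("wrap_to_sphere: radial extent %.3g exceeds pi*R = %.3g (over-wrap past the antipode)",
          max(rho), pi * R)
  len <- vnorm(net$vertices[net$beams[, 2], , drop = FALSE] -
                 net$vertices[net$beams[, 1], , drop = FALSE])
  k <- pmax(1L, as.integer(ceiling((len / R) / max_angle)))
  sub <- subdivide_network(net, k)
  p <- sub$vertices
  rho <- sqrt(p[, 1]^2 + p[, 2]^2)
  phi <- atan2(p[, 2], p[, 1])
  psi <- rho / R
  sub$vertices <- cbind(R * sin(psi) * cos(phi),
                        R * sin(psi) * sin(phi),
                        R * cos(psi))
  sub
}

# closed-form closest point on triangles (Ericson's Voronoi-region walk),
# vectorized over triangles for a single query point; regions are claimed in
# the canonical sequential order via a `done` mask
closest_on_triangles <- function(p, va, vb, vc) {
  n <- nrow(va)
  ab <- vb - va; ac <- vc - va
  pm <- matrix(p, n, 3, byrow = TRUE)
  ap <- pm - va
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- pm - vb
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- pm - vc
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  q <- matrix(0, n, 3); done <- logical(n)
  take <- function(mask, val) {
    m <- which(mask & !done)
    if (length(m)) { q[m, ] <<- val[m, , drop = FALSE]; done[m] <<- TRUE }
  }
  take(d1 <= 0 & d2 <= 0, va)                                   # corner A
  take(d3 >= 0 & d4 <= d3, vb)                                  # corner B
  vc_ <- d1 * d4 - d3 * d2
  take(vc_ <= 0 & d1 >= 0 & d3 <= 0, va + (d1 / (d1 - d3)) * ab)  # edge AB
  take(d6 >= 0 & d5 <= d6, vc)                                  # corner C
  vb_ <- d5 * d2 - d1 * d6
  take(vb_ <= 0 & d2 >= 0 & d6 <= 0, va + (d2 / (d2 - d6)) * ac)  # edge AC
  va_ <- d3 * d6 - d5 * d4
  tBC <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  take(va_ <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, vb + tBC * (vc - vb))  # edge BC
  denom <- va_ + vb_ + vc_
  qin <- va + (vb_ / denom) * ab + (vc_ / denom) * ac           # interior
  rest <- which(!done)
  q[rest, ] <- qin[rest, , drop = FALSE]
  q
}

#' Closest point on a triangle surface
#'
#' Global minimizer of the distance from `p` to the surface. A
#' bounding-sphere prune (triangle centroid + circumradius lower bound)
#' accelerates the exact per-triangle computation; by construction the
#' result equals the exhaustive search over all triangles.
#'
#' @param p a single query point (length-3) or n x 3 matrix.
#' @param surf a [tri_surface()].
#' @param faces optional integer vector restricting the search to a face
#'   subset.
#' @return for a single point, a list with `point`, `dist`, `face`; for a
#'   matrix, a list with `points` (n x 3), `dist` (n), `face` (n).
#' @export
closest_point_on_surface <- function(p, surf, faces = NULL) {
  if (!nrow(surf$faces)) stopf("closest_point_on_surface: empty surface")
  single <- is.null(dim(p))
  p <- as_points(p)
  fidx <- if (is.null(faces)) seq_len(nrow(surf$faces)) else as.integer(faces)
  fa <- surf$vertices[surf$faces[fidx, 1], , drop = FALSE]
  fb <- surf$vertices[surf$faces[fidx, 2], , drop = FALSE]
  fc <- surf$vertices[surf$faces[fidx, 3], , drop = FALSE]
  cen <- (fa + fb + fc) / 3
  rad <- pmax(pmax(vnorm(fa - cen), vnorm(fb - cen)), vnorm(fc - cen))
  out_q <- matrix(0, nrow(p), 3)
  out_d <- numeric(nrow(p)); out_f <- integer(nrow(p))
  for (i in seq_len(nrow(p))) {
    dc <- sqrt((cen[, 1] - p[i, 1])^2 + (cen[, 2] - p[i, 2])^2 +
                 (cen[, 3] - p[i, 3])^2)
    ub <- min(dc + rad)             # guaranteed achievable distance
    cand <- which(dc - rad <= ub + 1e-12)
    q <- closest_on_triangles(p[i, ], fa[cand, , drop = FALSE],
                              fb[cand, , drop = FALSE], fc[cand, , drop = FALSE])
    d <- sqrt((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2 + (q[, 3] - p[i, 3])^2)
    j <- which.min(d)
    out_q[i, ] <- q[j, ]; out_d[i] <- d[j]; out_f[i] <- fidx[cand[j]]
  }
  if (single) list(point = out_q[1, ], dist = out_d[1], face = out_f[1])
  else list(points = out_q, dist = out_d, face = out_f)
}

#' Project a beam network onto a surface by smallest distance
#'
#' Every vertex (and, after subdivision, every interior beam sample) is
#' replaced by its closest point on the target surface; connectivity is
#' unchanged. With `bottom_only = TRUE` the projection is restricted to
#' faces whose outward normal has a negative z component, matching the
#' "project onto the bottom of the organ" convention when the organ apex
#' points down.
#'
#' @param net a [beam_network()] (typically a curved sheet positioned to
#'   intersect the target slightly).
#' @param surf target [tri_surface()].
#' @param subdiv subdivide each beam into this many segments before
#'   projecting (1 = vertices only).
#' @param bottom_only restrict to downward-facing triangles.
#' @return the projected [beam_network()].
#' @export
project_network_to_surface <- function(net, surf, subdiv = 1L,
                                       bottom_only = FALSE) {
  faces <- NULL
  if (bottom_only) {
    nrm <- face_normals(surf)
    faces <- which(nrm[, 3] < 0)
    if (!length(faces)) stopf("no downward-facing triangles on the target surface")
  }
  if (subdiv > 1L) net <- subdivide_network(net, subdiv)
  cp <- closest_point_on_surface(net$vertices, surf, faces = faces)
  net$vertices <- cp$points
  net
}

#' Synthetic heart-like organ surface
#'
#' Deterministic closed, watertight, smooth blob standing in for a
#' repository organ model: the union of two offset spheres (the "ventricles")
#' blended with a tapered capsule apex pointing down (-z), perturbed
#' slightly by the seed. Intended as a projection target for
#' [project_network_to_surface()]. This is a synthetic fixture, not an
#' anatomical model.
#'
#' @param seed integer seed controlling the jitter of the lobe layout.
#' @param size overall scale (mm); lobe radii are fractions of it.
#' @param spacing voxel size used for surface extraction; default `size / 40`
#'   yields a mesh of roughly 5000 faces.
#' @return a [tri_surface()] with attribute `"sdf"` (the generating signed
#'   distance function).
#' @export
gen_synthetic_organ <- function(seed = 1, size = 20, spacing = NULL) {
  if (is.null(spacing)) spacing <- size / 40
  jit <- with_seed(seed, runif(6, -0.03, 0.03)) * size
  r1 <- 0.32 * size; r2 <- 0.27 * size
  c1 <- c(-0.12 * size + jit[1], jit[2], 0.10 * size + jit[3])
  c2 <- c(0.14 * size + jit[4], jit[5], 0.12 * size + jit[6])
  apex_top <- c(0, 0, 0.05 * size)
  apex_bot <- c(0.02 * size, 0, -0.35 * size)
  smooth_min <- function(a, b, k = 0.08 * size) {
    h <- clamp(0.5 + 0.5 * (b - a) / k, 0, 1)
    b + (a - b) * h - k * h * (1 - h)
  }
  fn <- function(p) {
    d <- smooth_min(sdf_sphere(p, c1, r1), sdf_sphere(p, c2, r2))
    smooth_min(d, sdf_capsule(p, apex_top, apex_bot, 0.16 * size))
  }
  lower <- c(-0.6, -0.5, -0.62) * size
  upper <- c(0.62, 0.5, 0.55) * size
  g <- grid_from_sdf(fn, lower, upper, spacing)
  surf <- extract_surface(g, 0)
  attr(surf, "sdf") <- fn
  surf
}

#' Wrap a planar auxetic mesh onto an organ surface
#'
#' Convenience pipeline for organ-conforming meshes: clip the planar mesh to
#' a circle, wrap the circular mesh onto a sphere (azimuthal-equidistant),
#' position the curved sheet so it sinks `intersection_depth` into the organ
#' from below, then project every sheet point onto the organ surface by
#' smallest distance (restricted to downward-facing triangles by default).
#'
#' @param net planar [beam_network()].
#' @param organ target [tri_surface()].
#' @param clip_radius circle radius (mm).
#' @param sphere_radius sphere radius (mm).
#' @param intersection_depth how far (mm) the organ sinks into the curved
#'   sheet before projection; default 5% of the organ's bounding-box height.
#' @param subdiv per-beam subdivision used for the projection.
#' @param bottom_only restrict projection to downward-facing faces.
#' @return the wrapped [beam_network()] lying on the organ surface.
#' @export
wrap_to_organ <- function(net, organ, clip_radius, sphere_radius,
                          intersection_depth = NULL, subdiv = 4L,
                          bottom_only = TRUE) {
  bbm <- apply(organ$vertices, 2, range)
  if (is.null(intersection_depth))
    intersection_depth <- 0.05 * (bbm[2, 3] - bbm[1, 3])
  ctr <- colMeans(bbm)
  mesh_ctr <- c(mean(range(net$vertices[, 1])), mean(range(net$vertices[, 2])), 0)
  clipped <- clip_to_circle(net, center = mesh_ctr, radius = clip_radius)
  clipped$vertices[, 1] <- clipped$vertices[, 1] - mean(range(clipped$vertices[, 1]))
  clipped$vertices[, 2] <- clipped$vertices[, 2] - mean(range(clipped$vertices[, 2]))
  cap <- wrap_to_sphere(clipped, sphere_radius)
  # the cap covers the +z pole; flip it under the organ and raise it so the
  # organ bottom sinks intersection_depth into the bowl
  cap <- transform_network(cap, rot = diag(c(1, 1, -1)))
  zmin_cap <- min(cap$vertices[, 3])
  cap <- transform_network(cap, shift = c(ctr[1], ctr[2],
                                          bbm[1, 3] - zmin_cap - intersection_depth))
  project_network_to_surface(cap, organ, subdiv = subdiv, bottom_only = bottom_only)
}
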