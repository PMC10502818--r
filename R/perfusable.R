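#' Channel-tree design
#'
#' Parameters of the hyperbolic-sine perfusable channel tree: a single
#' sinh-profile channel descending from a central inlet, copied `n_copies`
#' times around the vertical axis, mirrored about the block midplane (the
#' mirrored rosette rotated by half the angular pitch), and re-joined at the
#' midplane by straight channels whose junction points lie on a circle of
#' diameter `D + 2 * amplitude * sinh(k)`.
#'
#' @param d inlet/outlet channel diameter (mm).
#' @param t channel thickness (diameter) at the midplane (mm).
#' @param D diameter of the central offset circle (mm); with
#'   `D = amplitude = 0` the tree degenerates to a straight axial channel.
#' @param n_copies number of channels around the axis (default 7).
#' @param amplitude sinh amplitude (mm).
#' @param block construct dimensions `(x, y, z)` (mm); channels span z.
#' @param k sinh steepness (dimensionless argument scale).
#' @param n_profile samples along each half-channel polyline.
#' @param sphere_radius,sphere_offset optional central hollow sphere carved
#'   with the channels (radius and channel clearance, mm).
#' @return An object of class `channel_design`.
#' @export
channel_design <- function(d = 1, t = 0.6, D = 0, n_copies = 7L, amplitude = 1.5,
                           block = c(10, 10, 12), k = 3, n_profile = 17L,
                           sphere_radius = 0, sphere_offset = 0.5) {
  if (d <= 0 || t <= 0) stopf("channel diameters d and t must be > 0")
  if (D < 0) stopf("central offset D must be >= 0")
  n_copies <- as.integer(n_copies)
  if (n_copies < 1) stopf("n_copies must be >= 1")
  if (amplitude < 0) stopf("amplitude must be >= 0")
  structure(list(d = d, t = t, D = D, n_copies = n_copies,
                 amplitude = amplitude, block = as.numeric(block), k = k,
                 n_profile = as.integer(n_profile),
                 sphere_radius = sphere_radius, sphere_offset = sphere_offset),
            class = "channel_design")
}

#' Generate a hyperbolic-sine channel tree
#'
#' One half-channel runs from the inlet on the axis at the block top down to
#' the midplane, its radial excursion growing as
#' `rho(s) = (D/2) * s + amplitude * sinh(k * s)` with `s` in `[0, 1]`. The
#' half-channel is copied `n_copies` times at angular pitch `2*pi/n_copies`,
#' mirrored about the midplane with the mirrored rosette rotated by half a
#' pitch, and matching midplane endpoints are joined by straight channels.
#' Channel thickness tapers linearly from `d` at the inlet/outlet hubs to
#' `t` at the midplane.
#'
#' @param c a [channel_design()].
#' @return a [beam_network()] with one inlet hub at `(0, 0, block[3])` and
#'   one outlet hub at the origin; `n_copies` disjoint inlet-to-outlet paths.
#' @export
gen_channel_tree <- function(c) {
  stopifnot(inherits(c, "channel_design"))
  H <- c$block[3]
  s <- seq(0, 1, length.out = c$n_profile)
  rho <- (c$D / 2) * s + c$amplitude * sinh(c$k * s)
  th_prof <- c$d + (c$t - c$d) * (s[-1] - diff(s) / 2)  # per-segment taper
  half <- function(theta, top) {
    z <- if (top) H - s * (H / 2) else s * (H / 2)
    pts <- cbind(rho * cos(theta), rho * sin(theta), z)
    n <- nrow(pts)
    beam_network(pts, cbind(seq_len(n - 1), seq_len(n - 1) + 1L), th_prof)
  }
  dth <- if (c$n_copies > 1) pi / c$n_copies else 0
  tops <- lapply(seq_len(c$n_copies) - 1L,
                 function(i) half(2 * pi * i / c$n_copies, TRUE))
  bots <- lapply(seq_len(c$n_copies) - 1L,
                 function(i) half(2 * pi * i / c$n_copies + dth, FALSE))
  links <- list()
  rend <- rho[length(rho)]
  for (i in seq_len(c$n_copies) - 1L) {
    a <- c(rend * cos(2 * pi * i / c$n_copies),
           rend * sin(2 * pi * i / c$n_copies), H / 2)
    b <- c(rend * cos(2 * pi * i / c$n_copies + dth),
           rend * sin(2 * pi * i / c$n_copies + dth), H / 2)
    if (sum((a - b)^2) > 1e-18)
      links[[length(links) + 1L]] <- beam_network(rbind(a, b), cbind(1L, 2L), c$t)
  }
  merge_networks(base::c(tops, bots, links), tol = 1e-9)
}

#' Alveolus design
#'
#' A budding alveolus: `n_buds` mini-spheres of radius `r` whose centers lie
#' on (or are rejection-sampled within) the sphere of radius `Rp - r`, at
#' mutual spacing at least `o`; an interior core sphere keeps the union a
#' single solid. Deterministic per seed.
#'
#' @param Rp parent sphere radius (mm).
#' @param r mini-sphere radius (mm), `< Rp`.
#' @param o minimum mini-sphere center spacing (mm).
#' @param n_buds number of mini-spheres.
#' @param wall shell thickness (mm) used by downstream hollowing.
#' @param seed integer seed (used by the `"random"` placement mode).
#' @param mode `"fibonacci"` (deterministic spherical Fibonacci layout,
#'   default) or `"random"` (uniform rejection sampling in the ball).
#' @param spacing voxel size (mm) for the rendered grid; default `Rp / 24`.
#' @return An object of class `alveolus_design`.
#' @export
alveolus_design <- function(Rp = 3, r = 1.2, o = 0.8, n_buds = 9L, wall = 0.3,
                            seed = 1L, mode = c("fibonacci", "random"),
                            spacing = NULL) {
  mode <- match.arg(mode)
  if (r <= 0 || r >= Rp) stopf("mini-sphere radius must satisfy 0 < r < Rp")
  n_buds <- as.integer(n_buds)
  if (n_buds < 1) stopf("n_buds must be >= 1")
  if (wall <= 0) stopf("wall thickness must be > 0")
  if (is.null(spacing)) spacing <- Rp / 24
  structure(list(Rp = Rp, r = r, o = o, n_buds = n_buds, wall = wall,
                 seed = as.integer(seed), mode = mode, spacing = spacing),
            class = "alveolus_design")
}

# spherical Fibonacci layout of n points on the unit sphere
fibonacci_sphere <- function(n) {
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  rr <- sqrt(pmax(1 - z^2, 0))
  ga <- pi * (3 - sqrt(5))
  th <- ga * (seq_len(n) - 1)
  cbind(rr * cos(th), rr * sin(th), z)
}

#' Generate a budding alveolus
#'
#' Renders the mini-sphere union as a signed-distance voxel grid. The
#' sphere list (centers and radii, including the interior core) is attached
#' as attributes `"centers"` and `"radii"`; these drive the analytic
#' offset-surface projection in [wrap_network_to_offset_surface()].
#'
#' @param a an [alveolus_design()].
#' @return a [voxel_grid()] of signed distances, centered on the origin.
#' @export
gen_alveolus <- function(a) {
  stopifnot(inherits(a, "alveolus_design"))
  Rc <- a$Rp - a$r
  if (a$n_buds == 1L) {
    centers <- matrix(0, 1, 3)
  } else if (a$mode == "fibonacci") {
    centers <- fibonacci_sphere(a$n_buds) * Rc
    if (nrow(centers) > 1) {
      dmin <- min(stats::dist(centers))
      if (dmin < a$o)
        stopf("cannot place %d buds at spacing %.3g (achieved %d at min spacing %.3g): reduce o or n_buds",
              a$n_buds, a$o, a$n_buds, dmin)
    }
  } else {
    centers <- matrix(numeric(0), 0, 3)
    with_seed(a$seed, {
      tries <- 0L
      while (nrow(centers) < a$n_buds && tries < 5000L) {
        tries <- tries + 1L
        cand <- runif(3, -1, 1)
        if (sum(cand^2) > 1) next
        cand <- cand * Rc
        if (!nrow(centers) ||
            min(vnorm(sweep(centers, 2, cand))) >= a$o)
          centers <- rbind(centers, cand)
      }
    })
    if (nrow(centers) < a$n_buds)
      stopf("cannot place %d buds at spacing %.3g: achieved %d", a$n_buds, a$o,
            nrow(centers))
  }
  radii <- rep(a$r, nrow(centers))
  if (a$n_buds > 1L && Rc >= max(a$spacing, 0.1 * a$r)) {
    centers <- rbind(centers, c(0, 0, 0))   # core sphere fills the interior
    radii <- c(radii, Rc)
  }
  ext <- a$Rp + 2 * a$spacing
  fn <- function(p) {
    d <- rep(Inf, nrow(p))
    for (i in seq_along(radii)) d <- pmin(d, sdf_sphere(p, centers[i, ], radii[i]))
    d
  }
  g <- grid_from_sdf(fn, rep(-ext, 3), rep(ext, 3), a$spacing)
  attr(g, "centers") <- centers
  attr(g, "radii") <- radii
  attr(g, "design") <- a
  g
}

#' Hollow out a solid by subtracting a scaled-down copy
#'
#' The stored field is resampled at `p / scale` (trilinear interpolation,
#' distances rescaled), which realizes the concentric scaled copy about the
#' grid's coordinate origin; the copy is then boolean-subtracted, leaving a
#' shell.
#'
#' @param g a [voxel_grid()] of signed distances whose solid contains the
#'   origin region (e.g. an alveolus centered at the origin).
#' @param scale shrink factor in `(0, 1)`.
#' @return a [voxel_grid()] holding the shell.
#' @export
hollow_shape <- function(g, scale) {
  if (scale <= 0 || scale >= 1) stopf("scale must be in (0, 1)")
  pts <- grid_centers(g) / scale
  inner <- scale * interp_grid(g, pts)
  voxel_grid(array(pmax(g$values, -inner), dim(g$values)), g$origin, g$spacing)
}

# trilinear interpolation of grid values at arbitrary points; outside points
# clamp to the border value (positive there for solids away from the border)
interp_grid <- function(g, pts) {
  sh <- dim(g$values)
  fx <- clamp((pts[, 1] - g$origin[1]) / g$spacing, 0, sh[1] - 1)
  fy <- clamp((pts[, 2] - g$origin[2]) / g$spacing, 0, sh[2] - 1)
  fz <- clamp((pts[, 3] - g$origin[3]) / g$spacing, 0, sh[3] - 1)
  i0 <- pmin(floor(fx), sh[1] - 2); j0 <- pmin(floor(fy), sh[2] - 2)
  k0 <- pmin(floor(fz), sh[3] - 2)
  if (sh[3] == 1L) k0 <- 0 * k0
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  at <- function(di, dj, dk) {
    kk <- pmin(k0 + dk, sh[3] - 1)
    g$values[1 + (i0 + di) + sh[1] * ((j0 + dj) + sh[2] * kk)]
  }
  (1 - tz) * ((1 - ty) * ((1 - tx) * at(0, 0, 0) + tx * at(1, 0, 0)) +
                ty * ((1 - tx) * at(0, 1, 0) + tx * at(1, 1, 0))) +
    tz * ((1 - ty) * ((1 - tx) * at(0, 0, 1) + tx * at(1, 0, 1)) +
            ty * ((1 - tx) * at(0, 1, 1) + tx * at(1, 1, 1)))
}

#' Capillary vessel-network design
#'
#' @param level icosahedron subdivision level `L >= 0`; each level divides
#'   every triangle into four, so face count is `20 * 4^L` and the vessel
#'   beam count `3 * faces`.
#' @param radius circumscribed-sphere radius (mm).
#' @param thick_ends,thick_mid beam thickness (mm) at the left/right ends of
#'   the inlet-outlet axis and at the middle (linear gradient).
#' @param top_enlarge scaling factor for the network ring around the topmost
#'   vertex (opens the inlet window; default 2).
#' @param n_interp equidistant interpolation points per beam (default 11,
#'   i.e. 10 sub-beams).
#' @param gap clearance (mm) between the wrapped vessels and the alveolar
#'   surface (default 0.25).
#' @return An object of class `vessel_design`.
#' @export
vessel_design <- function(level = 1L, radius = 3, thick_ends = 0.4,
                          thick_mid = 0.2, top_enlarge = 2, n_interp = 11L,
                          gap = 0.25) {
  level <- as.integer(level)
  if (level < 0) stopf("subdivision level must be >= 0")
  if (thick_ends <= 0 || thick_mid <= 0) stopf("thicknesses must be > 0")
  n_interp <- as.integer(n_interp)
  if (n_interp < 2) stopf("n_interp must be >= 2")
  structure(list(level = level, radius = radius, thick_ends = thick_ends,
                 thick_mid = thick_mid, top_enlarge = top_enlarge,
                 n_interp = n_interp, gap = gap),
            class = "vessel_design")
}

# unit icosahedron (vertices on the unit sphere) and its 20 faces
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# midpoint subdivision on the flat faces (no sphere projection)
subdivide_faces <- function(mesh, levels) {
  for (l in seq_len(levels)) {
    v <- mesh$vertices; f <- mesh$faces
    ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    keys <- ekey(edges[, 1], edges[, 2])
    ukeys <- unique(keys)
    mid_of <- match(keys, ukeys) + nrow(v)
    ue <- edges[!duplicated(keys), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    nf <- nrow(f)
    m12 <- mid_of[seq_len(nf)]
    m23 <- mid_of[nf + seq_len(nf)]
    m31 <- mid_of[2 * nf + seq_len(nf)]
    mesh <- list(vertices = rbind(v, mids),
                 faces = rbind(cbind(f[, 1], m12, m31),
                               cbind(m12, f[, 2], m23),
                               cbind(m31, m23, f[, 3]),
                               cbind(m12, m23, m31)))
  }
  mesh
}

#' Generate the icosahedral capillary network
#'
#' A regular icosahedron is midpoint-subdivided `level` times (each triangle
#' into four identical triangles); for every triangle, beams join its
#' geometric center to its three edge midpoints, giving the hexagonal
#' capillary net. The ring of network vertices around the topmost
#' icosahedron vertex is scaled by `top_enlarge` about that vertex to open
#' the inlet window; beam thickness is graded linearly from `thick_ends` at
#' the extreme x positions to `thick_mid` at the middle; finally every beam
#' is interpolated into `n_interp` equidistant points (`n_interp - 1`
#' sub-beams) and each point is radially projected onto the circumscribed
#' sphere.
#'
#' @param v a [vessel_design()].
#' @return a [beam_network()] on the sphere of radius `radius`, with the
#'   pre-interpolation combinatorial net attached as attribute `"combinatorial"`.
#' @export
gen_icosa_network <- function(v) {
  stopifnot(inherits(v, "vessel_design"))
  mesh <- subdivide_faces(icosahedron(), v$level)
  verts <- mesh$vertices * v$radius
  f <- mesh$faces
  nf <- nrow(f)
  cent <- (verts[f[, 1], , drop = FALSE] + verts[f[, 2], , drop = FALSE] +
             verts[f[, 3], , drop = FALSE]) / 3
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  keys <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  ukeys <- unique(keys)
  eid <- match(keys, ukeys)
  ue <- edges[!duplicated(keys), , drop = FALSE]
  mids <- (verts[ue[, 1], , drop = FALSE] + verts[ue[, 2], , drop = FALSE]) / 2
  nmid <- nrow(mids)
  pts <- rbind(cent, mids)             # 1..nf centroids, then edge midpoints
  beams <- cbind(rep(seq_len(nf), 3), nf + eid)
  # open the inlet window: scale the vertices belonging to faces/edges
  # incident to the topmost icosahedron vertex about that vertex
  topv <- which.max(verts[, 3])
  inc_face <- which(f[, 1] == topv | f[, 2] == topv | f[, 3] == topv)
  inc_edge <- which(ue[, 1] == topv | ue[, 2] == topv)
  sel <- c(inc_face, nf + inc_edge)
  tv <- verts[topv, ]
  pts[sel, ] <- matrix(tv, length(sel), 3, byrow = TRUE) +
    v$top_enlarge * (pts[sel, , drop = FALSE] -
                       matrix(tv, length(sel), 3, byrow = TRUE))
  # thickness gradient along x (the inlet-outlet axis)
  mid_x <- (pts[beams[, 1], 1] + pts[beams[, 2], 1]) / 2
  xmax <- max(abs(mid_x))
  th <- v$thick_mid + (v$thick_ends - v$thick_mid) * abs(mid_x) / max(xmax, 1e-12)
  comb <- beam_network(pts, beams, th)
  out <- subdivide_network(comb, v$n_interp - 1L)
  rr <- vnorm(out$vertices)
  out$vertices <- out$vertices * (v$radius / pmax(rr, 1e-12))
  attr(out, "combinatorial") <- comb
  attr(out, "design") <- v
  out
}

#' Wrap a vessel network onto an offset alveolar surface
#'
#' Every vessel point is projected to the closest point of the alveolar
#' surface dilated outward by `gap`, so the final vessels hug the alveolus
#' at the prescribed clearance. When `alveolus` carries the sphere list from
#' [gen_alveolus()] the projection is analytic (closest point on the nearest
#' mini-sphere inflated by `gap`, exact away from the concave creases);
#' a [tri_surface()] target uses [closest_point_on_surface()] plus an
#' outward normal offset.
#'
#' @param net vessel [beam_network()] concentric with the alveolus.
#' @param alveolus a [gen_alveolus()] grid (with sphere attributes) or a
#'   [tri_surface()].
#' @param gap offset (mm), default 0.25.
#' @return the wrapped [beam_network()] (connectivity unchanged).
#' @export
wrap_network_to_offset_surface <- function(net, alveolus, gap = 0.25) {
  p <- net$vertices
  if (inherits(alveolus, "voxel_grid") && !is.null(attr(alveolus, "centers"))) {
    centers <- attr(alveolus, "centers")
    radii <- attr(alveolus, "radii") + gap
    d <- matrix(0, nrow(p), nrow(centers))
    for (i in seq_len(nrow(centers)))
      d[, i] <- vnorm(sweep(p, 2, centers[i, ])) - radii[i]
    best <- max.col(-d)
    ctr <- centers[best, , drop = FALSE]
    dir <- p - ctr
    nn <- pmax(vnorm(dir), 1e-12)
    net$vertices <- ctr + dir * (radii[best] / nn)
  } else if (inherits(alveolus, "tri_surface")) {
    cp <- closest_point_on_surface(p, alveolus)
    dir <- p - cp$points
    nn <- vnorm(dir)
    dir <- ifelse(nn > 1e-12, 1, NA) * dir / pmax(nn, 1e-12)
    dir[is.na(dir)] <- 0
    net$vertices <- cp$points + gap * dir
  } else stopf("alveolus must be a gen_alveolus() grid or a tri_surface")
  net
}

#' Assemble a perfusable construct by boolean carving
#'
#' Renders the outer solid on a voxel grid and carves, in order, the
#' channel/vessel network, an optional central cavity (sphere or alveolar
#' pocket), and vertical inlet/outlet port cylinders drilled from the top
#' face down to chosen branch points of the network. The carved void from
#' the inlet must form one connected component with the outlet (checked by
#' [construct_is_perfusable()], not here).
#'
#' @param outer outer solid: `list(type = "box", dims = c(x, y, z))` or
#'   `list(type = "cylinder", r =, h =)`, based at the origin (z in `[0, h]`).
#' @param channels optional [beam_network()] carved as channels.
#' @param cavity optional `list(type = "sphere", center =, r =)` or an
#'   alveolus [voxel_grid()] (its solid, dilated by `cavity_clearance`,
#'   becomes the pocket).
#' @param ports number of ports to drill (0, 1 or 2) at the branch points
#'   nearest the two antipodal top positions; or a list of
#'   `list(x =, y =, radius =)` specs (each must overlap a branch point).
#' @param port_radius radius (mm) of auto-placed ports.
#' @param cavity_clearance dilation (mm) of an alveolar pocket.
#' @param spacing voxel size (mm); default resolves the thinnest channel.
#' @return a [voxel_grid()] of the carved construct with attribute
#'   `"ports"` (matrix of port x, y, radius).
#' @export
assemble_perfusable_construct <- function(outer, channels = NULL, cavity = NULL,
                                          ports = 0L, port_radius = NULL,
                                          cavity_clearance = 0,
                                          spacing = NULL) {
  if (is.null(spacing))
    spacing <- if (!is.null(channels)) min(channels$thickness) / 3 else
      (if (outer$type == "box") min(outer$dims) else outer$r) / 24
  if (outer$type == "box") {
    dims <- as.numeric(outer$dims)
    g <- grid_from_sdf(function(p) sdf_box(p, c(0, 0, 0) - c(dims[1:2] / 2, 0),
                                           c(dims[1:2] / 2, dims[3])),
                       -c(dims[1:2] / 2, 0) - 2 * spacing,
                       c(dims[1:2] / 2, dims[3]) + 2 * spacing, spacing)
    topz <- dims[3]
  } else if (outer$type == "cylinder") {
    g <- grid_from_sdf(function(p) sdf_cylinder(p, c(0, 0, outer$h / 2),
                                                outer$r, outer$h),
                       c(-outer$r, -outer$r, 0) - 2 * spacing,
                       c(outer$r, outer$r, outer$h) + 2 * spacing, spacing)
    topz <- outer$h
  } else stopf("outer$type must be 'box' or 'cylinder'")

  if (!is.null(channels)) {
    cg <- voxelize_network(channels, grid = g)
    g <- boolean_op(g, cg, "subtract")
  }
  if (!is.null(cavity)) {
    cav <- if (inherits(cavity, "voxel_grid")) {
      voxel_grid(array(interp_grid(cavity, grid_centers(g)) - cavity_clearance,
                       dim(g$values)), g$origin, g$spacing)
    } else if (identical(cavity$type, "sphere")) {
      grid_from_sdf(function(p) sdf_sphere(p, cavity$center, cavity$r),
                    g$origin - g$spacing / 2,
                    g$origin - g$spacing / 2 + dim(g$values) * g$spacing,
                    g$spacing)
    } else stopf("unsupported cavity spec")
    g <- boolean_op(g, cav, "subtract")
  }

  port_tab <- matrix(numeric(0), 0, 3)
  if (is.numeric(ports) && length(ports) == 1L) {
    nport <- as.integer(ports)
    if (nport > 0L) {
      if (is.null(channels)) stopf("ports need a channel/vessel network")
      if (is.null(port_radius)) port_radius <- max(channels$thickness) / 2
      deg <- tabulate(as.vector(channels$beams), nrow(channels$vertices))
      branch <- which(deg >= 3L)
      if (!length(branch)) stopf("no branch points available for ports")
      bp <- channels$vertices[branch, , drop = FALSE]
      span <- max(abs(bp[, 1]))
      targets <- rbind(c(span, 0), c(-span, 0))[seq_len(min(nport, 2L)), , drop = FALSE]
      for (k in seq_len(nrow(targets))) {
        j <- which.min((bp[, 1] - targets[k, 1])^2 + (bp[, 2] - targets[k, 2])^2)
        port_tab <- rbind(port_tab, c(bp[j, 1], bp[j, 2], port_radius))
      }
    }
  } else if (is.list(ports)) {
    if (is.null(channels)) stopf("ports need a channel/vessel network")
    deg <- tabulate(as.vector(channels$beams), nrow(channels$vertices))
    bp <- channels$vertices[deg >= 3L, , drop = FALSE]
    for (p in ports) {
      dd <- sqrt((bp[, 1] - p$x)^2 + (bp[, 2] - p$y)^2)
      if (!length(dd) || min(dd) > p$radius)
        stopf("port at (%.3g, %.3g) does not intersect any branch point", p$x, p$y)
      port_tab <- rbind(port_tab, c(p$x, p$y, p$radius))
    }
  }
  for (k in seq_len(nrow(port_tab))) {
    zs <- c(min(g$origin[3], 0), topz + 2 * spacing)
    cyl <- grid_from_sdf(function(p)
      sdf_capsule(p, c(port_tab[k, 1], port_tab[k, 2], zs[1]),
                  c(port_tab[k, 1], port_tab[k, 2], zs[2]), port_tab[k, 3]),
      g$origin - g$spacing / 2,
      g$origin - g$spacing / 2 + dim(g$values) * g$spacing, g$spacing)
    # drill from the top face down to just past the branch point depth
    zcut <- if (!is.null(channels)) {
      deg <- tabulate(as.vector(channels$beams), nrow(channels$vertices))
      bpv <- channels$vertices[deg >= 3L, , drop = FALSE]
      near <- which.min((bpv[, 1] - port_tab[k, 1])^2 + (bpv[, 2] - port_tab[k, 2])^2)
      bpv[near, 3] - port_tab[k, 3]
    } else 0
    zmask <- grid_from_sdf(function(p) zcut - p[, 3],
                           g$origin - g$spacing / 2,
                           g$origin - g$spacing / 2 + dim(g$values) * g$spacing,
                           g$spacing)
    bore <- boolean_op(cyl, zmask, "subtract")  # cylinder above zcut only
    g <- boolean_op(g, bore, "subtract")
  }
  attr(g, "ports") <- port_tab
  g
}

#' Check inlet-to-outlet perfusability of a carved construct
#'
#' Flood-fills the void space (6-connectivity) and reports whether the void
#' adjacent to `from` and `to` (two xyz probe points, e.g. just inside the
#' inlet and outlet hubs) belongs to one connected component.
#'
#' @param g carved construct [voxel_grid()].
#' @param from,to probe points (mm).
#' @return `TRUE`/`FALSE`, with attribute `"n_void_components"`.
#' @export
construct_is_perfusable <- function(g, from, to) {
  lab <- label_components(!grid_indicator(g))  # void voxels
  locate <- function(p) {
    idx <- pmin(pmax(round((as.numeric(p) - g$origin) / g$spacing) + 1, 1),
                dim(g$values))
    lab[idx[1], idx[2], idx[3]]
  }
  la <- locate(from); lb <- locate(to)
  ok <- la > 0L && lb > 0L && la == lb
  attr(ok, "n_void_components") <- max(lab)
  ok
}
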