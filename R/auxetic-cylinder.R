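#' Cylindrical auxetic mesh design
#'
#' Parameters of the cylindrical auxetic generators. The cylinder axis is z,
#' ring index 0 sits at z = 0. `h` counts the horizontal rings from top to
#' bottom, `v` the vertical lines per ring (`v` must be even so the
#' alternating pattern closes seamlessly around the circumference), `t` the
#' element thickness.
#'
#' @param kind `"reentrant_vertical"`, `"reentrant_horizontal"`,
#'   `"sinusoidal"` or `"pinwheel"`.
#' @param R cylinder radius (mm).
#' @param H cylinder height (mm).
#' @param h number of horizontal rings, `>= 2`.
#' @param v number of vertical lines per ring, `>= 2`, even.
#' @param t element thickness (mm).
#' @param amplitude corner offset / sine amplitude (mm); default a quarter of
#'   the baseline separation along the offset direction (angular separation
#'   `2*pi*R/v` for vertical and sinusoidal kinds, ring separation
#'   `H/(h - 1)` for the horizontal re-entrant kind).
#' @return An object of class `cylinder_design`.
#' @export
cylinder_design <- function(kind = c("reentrant_vertical", "reentrant_horizontal",
                                     "sinusoidal", "pinwheel"),
                            R = 4, H = 12, h = 6, v = 12, t = 0.3,
                            amplitude = NULL) {
  kind <- match.arg(kind)
  if (R <= 0 || H <= 0 || t <= 0) stopf("R, H and t must be > 0")
  h <- as.integer(h); v <- as.integer(v)
  if (h < 2 || v < 2) stopf("h and v must be >= 2")
  if (v %% 2 != 0)
    stopf("v must be even: the alternating pattern cannot close the seam with v = %d", v)
  sep <- if (kind == "reentrant_vertical") 2 * pi * R / v else H / (h - 1)
  if (is.null(amplitude)) amplitude <- 0.25 * sep
  if (amplitude < 0 || amplitude >= sep / 2)
    stopf("amplitude must lie in [0, %.3g) for this design", sep / 2)
  structure(list(kind = kind, R = R, H = H, h = h, v = v, t = t,
                 amplitude = amplitude),
            class = "cylinder_design")
}

#' Wrap planar points onto a cylinder
#'
#' Arc-length-preserving map from the unrolled plane to the cylinder coat:
#' `(x, y) -> (R cos(x / R), R sin(x / R), y)`. The planar x coordinate
#' becomes arc length around the circumference; y becomes the axial (z)
#' coordinate. Every mapped point lies at distance exactly `R` from the
#' z-axis.
#'
#' @param p n x 3 point matrix (or length-3 vector); z is ignored.
#' @param R cylinder radius (mm), `> 0`.
#' @return n x 3 matrix of wrapped points.
#' @export
wrap_to_cylinder <- function(p, R) {
  if (R <= 0) stopf("R must be > 0")
  p <- as_points(p)
  th <- p[, 1] / R
  cbind(R * cos(th), R * sin(th), p[, 2])
}

#' Inverse of [wrap_to_cylinder()]
#'
#' Maps cylinder-coat points back to the unrolled plane with
#' `x = R * atan2(y, x)` in `[0, 2*pi*R)` and `y = z`.
#' @param p n x 3 point matrix.
#' @param R cylinder radius (mm).
#' @export
unwrap_from_cylinder <- function(p, R) {
  p <- as_points(p)
  th <- atan2(p[, 2], p[, 1]) %% (2 * pi)
  cbind(R * th, p[, 3], 0)
}

# Wrap an unrolled planar network (x in [0, 2*pi*R), y axial) onto the
# cylinder: each beam is subdivided into ceil(spanned angle / 5 deg)
# segments, interpolated across the seam by the shorter way, every sample
# wrapped, and coincident points merged so the seam closes.
wrap_unrolled_network <- function(net, R, seam = TRUE, max_angle = 5 * pi / 180) {
  circ <- 2 * pi * R
  chains <- vector("list", nrow(net$beams))
  for (i in seq_len(nrow(net$beams))) {
    a <- net$vertices[net$beams[i, 1], 1:2]
    b <- net$vertices[net$beams[i, 2], 1:2]
    if (seam) {
      if (b[1] - a[1] > circ / 2) b[1] <- b[1] - circ
      if (a[1] - b[1] > circ / 2) b[1] <- b[1] + circ
    }
    k <- max(1L, as.integer(ceiling(abs(b[1] - a[1]) / R / max_angle)))
    s <- seq(0, 1, length.out = k + 1)
    chains[[i]] <- cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]))
  }
  nets <- lapply(seq_along(chains), function(i) {
    p3 <- wrap_to_cylinder(cbind(chains[[i]], 0), R)
    n <- nrow(p3)
    beam_network(p3, cbind(seq_len(n - 1), seq_len(n - 1) + 1L),
                 net$thickness[i])
  })
  merge_networks(nets, tol = 1e-9)
}

#' Generate a cylindrical auxetic mesh
#'
#' Builds the corner-point lattice of the chosen topology in the unrolled
#' plane (circumference `2*pi*R` by height `H`), closes it periodically
#' around the seam, then translates every (subdivided) beam onto the
#' cylinder coat with the arc-length-preserving wrapping map, so straight
#' corner-to-corner beams become chords following the cylinder and ring
#' beams become arcs.
#'
#' * **reentrant_vertical**: `v` vertical zigzag lines whose corners
#'   alternate by `+-amplitude` in the angular direction (sign flipped on
#'   consecutive lines, so the corners lie on parallel circles with a phase
#'   shift); facing corner pairs of neighboring lines are joined by arcs on
#'   alternating rings (`h` rings top to bottom).
#' * **reentrant_horizontal**: `h` zigzag rings, each composed of two
#'   circles `amplitude` above/below the ring line with angular step
#'   `2*pi/v` and a phase shift of `pi/v` between the two circles; facing
#'   corners of neighboring rings are joined by `v` vertical beams on
#'   alternating angular positions.
#' * **sinusoidal**: a family of `v` vertical sinusoids (period twice the
#'   angular baseline separation, alternate lines phase-shifted by half a
#'   period) crossed and fused with `h` sinusoidal rings (an integer number
#'   `v/2` of periods around the circumference).
#' * **pinwheel**: the same two sinusoid families with zero relative phase.
#'
#' The returned network carries the unrolled corner lattice as attribute
#' `"unrolled"` (used by the unwrap round-trip checks).
#'
#' @param design a [cylinder_design()].
#' @return a [beam_network()] whose vertices all lie at distance `R` from
#'   the z-axis.
#' @export
gen_cylindrical_auxetic <- function(design) {
  stopifnot(inherits(design, "cylinder_design"))
  R <- design$R; H <- design$H; v <- design$v; h <- design$h
  A <- design$amplitude; circ <- 2 * pi * R
  sepx <- circ / v
  unrolled <- switch(
    design$kind,
    reentrant_vertical = {
      core <- reentrant_core((seq_len(v) - 1) * sepx,
                             seq(0, H, length.out = 2L * h),
                             A, style = "reentrant", periodic_base = TRUE)
      beam_network(cbind(core$uw, 0), core$beams, design$t)
    },
    reentrant_horizontal = {
      # baselines are rings along z; corner rows run around the circumference
      nr <- 2L * v
      core <- reentrant_core(seq(0, H, length.out = h),
                             (seq_len(nr) - 1) * (circ / nr),
                             A, style = "reentrant", periodic_row = TRUE)
      beam_network(cbind(core$uw[, 2], core$uw[, 1], 0)[, c(1, 2, 3)],
                   core$beams, design$t)
    },
    sinusoidal = ,
    pinwheel = {
      # sinusoidal rings waving axially (v/2 periods around the seam),
      # neighboring rings in anti-phase (sinusoidal) or in phase (pinwheel),
      # joined by vertical beams at the wide extreme positions
      phases <- if (design$kind == "sinusoidal") pi * (seq_len(h) - 1) else rep(0, h)
      core <- sinusoid_core(seq(0, H, length.out = h), A, 2 * sepx, phases,
                            c(0, circ), design$t, periodic = FALSE)
      swap_uw(core, swap = TRUE)
    })
  out <- wrap_unrolled_network(unrolled, R, seam = TRUE)
  attr(out, "unrolled") <- unrolled
  attr(out, "design") <- design
  out
}
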