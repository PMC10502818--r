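#' Planar auxetic mesh design
#'
#' Parameter container for the four planar auxetic topologies. `n1` counts
#' the vertical elements (baselines), `n2` the horizontal elements, `t` the
#' element thickness. Vertical baselines run along y; axial stretch in the
#' mechanics screen is applied along y and lateral expansion read along x.
#'
#' @param kind `"reentrant"`, `"arrowhead"`, `"sinusoidal"` or `"pinwheel"`.
#' @param n1 number of vertical elements (baselines), `>= 1`.
#' @param n2 number of horizontal elements, `>= 1`.
#' @param t element thickness (mm), `> 0`.
#' @param width,height mesh extents (mm); the generated network spans exactly
#'   `[0, width] x [0, height]` in the z = 0 plane.
#' @param amplitude vertex offset / sine amplitude (mm). Default
#'   `0.25 * width / max(n1 - 1, 1)` (a quarter of the baseline separation);
#'   must stay below half the separation to avoid self-intersection.
#' @return An object of class `planar_design`.
#' @export
planar_design <- function(kind = c("reentrant", "arrowhead", "sinusoidal", "pinwheel"),
                          n1 = 6, n2 = 6, t = 0.3, width = 10, height = 10,
                          amplitude = NULL) {
  kind <- match.arg(kind)
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 1 || n2 < 1) stopf("n1 and n2 must be >= 1")
  if (t <= 0) stopf("element thickness t must be > 0")
  if (width <= 0 || height <= 0) stopf("width and height must be > 0")
  sep <- width / max(n1 - 1, 1)
  if (is.null(amplitude)) amplitude <- 0.25 * sep
  if (amplitude < 0) stopf("amplitude must be >= 0")
  if (amplitude >= sep / 2)
    stopf("amplitude %.3g >= half the baseline separation %.3g: self-intersecting design",
          amplitude, sep / 2)
  structure(list(kind = kind, n1 = n1, n2 = n2, t = t, width = width,
                 height = height, amplitude = amplitude),
            class = "planar_design")
}

# Shared re-entrant / arrowhead corner-point lattice in (u, w) coordinates:
# baselines are lines of constant u at base_pos, corner rows lie at row_pos
# along w, and vertices are offset along u by +-A. `flip_base` alternates the
# offset sign between consecutive baselines (re-entrant); arrowhead keeps the
# same pattern on every baseline and connects negative-offset corners to the
# two neighboring positive-offset corners of the next baseline.
reentrant_core <- function(base_pos, row_pos, A, style = c("reentrant", "arrowhead"),
                           periodic_base = FALSE, periodic_row = FALSE) {
  style <- match.arg(style)
  nb <- length(base_pos); nr <- length(row_pos)
  s <- rep_len(c(-1, 1), nr)                      # row alternation
  f <- if (style == "reentrant") rep_len(c(1, -1), nb) else rep(1, nb)
  vid <- function(i, j) (i - 1L) * nr + j
  u <- as.vector(vapply(seq_len(nb),
                        function(i) base_pos[i] + A * s * f[i],
                        numeric(nr)))
  w <- rep(row_pos, times = nb)
  beams <- list()
  # zigzag along each baseline
  i <- rep(seq_len(nb), each = nr - 1)
  j <- rep(seq_len(nr - 1), times = nb)
  beams$zig <- cbind(vid(i, j), vid(i, j + 1))
  if (periodic_row)
    beams$zigclose <- cbind(vid(seq_len(nb), nr), vid(seq_len(nb), 1L))
  # cross beams between consecutive baselines
  pairs <- if (periodic_base) cbind(seq_len(nb), c(seq_len(nb)[-1], 1L))
           else cbind(seq_len(nb - 1L), seq_len(nb - 1L) + 1L)
  cross <- list()
  for (k in seq_len(nrow(pairs))) {
    i1 <- pairs[k, 1]; i2 <- pairs[k, 2]
    if (style == "reentrant") {
      # join the wide (outward-offset) vertex pairs so the cell between two
      # consecutive connectors is the re-entrant bow-tie (walls bulge inward)
      rows <- which(s == -f[i1])
      cross[[k]] <- cbind(vid(i1, rows), vid(i2, rows))
    } else {
      rows <- which(s == -1)     # negative-offset corners shoot diagonals
      lo <- rows - 1L; hi <- rows + 1L
      if (periodic_row) {
        lo[lo < 1L] <- nr; hi[hi > nr] <- 1L
        keeplo <- keephi <- rep(TRUE, length(rows))
      } else {
        keeplo <- lo >= 1L; keephi <- hi <= nr
      }
      cross[[k]] <- rbind(cbind(vid(i1, rows[keeplo]), vid(i2, lo[keeplo])),
                          cbind(vid(i1, rows[keephi]), vid(i2, hi[keephi])))
    }
  }
  beams$cross <- do.call(rbind, cross)
  list(uw = cbind(u, w), beams = do.call(rbind, beams),
       nb = nb, nr = nr, s = s, f = f)
}

# Sinusoidal-ligament lattice in (u, w) coordinates: one sinusoid per
# baseline, waving in u as a function of w with the given phases, plus
# straight connectors between neighboring sinusoids at the extreme-offset
# rows where the pair is widest (bow-tie cells for the anti-phase family;
# the zero-phase pinwheel family keeps the same alternating connector rule).
# Connector rows land exactly on curve sample points (step = period / 32),
# so merging fuses them into shared vertices.
sinusoid_core <- function(base_pos, A, period, phases, w_range, t,
                          periodic = FALSE) {
  nb <- length(base_pos)
  step <- period / 32
  wseq <- seq(w_range[1], w_range[2], by = step)
  if (tail(wseq, 1) < w_range[2] - 1e-12) wseq <- c(wseq, w_range[2])
  ufun <- function(i, w) base_pos[i] + A * sin(2 * pi * w / period + phases[i])
  nets <- lapply(seq_len(nb), function(i) {
    n <- length(wseq)
    beam_network(cbind(ufun(i, wseq), wseq, 0),
                 cbind(seq_len(n - 1), seq_len(n - 1) + 1L), t)
  })
  # extreme rows: sin = +1 at w = period/4 + k*period, -1 at 3*period/4 + ...
  wex <- seq(w_range[1] + period / 4, w_range[2] - if (periodic) step else 0,
             by = period / 2)
  pairs <- if (periodic) cbind(seq_len(nb), c(seq_len(nb)[-1], 1L))
           else cbind(seq_len(nb - 1L), seq_len(nb - 1L) + 1L)
  for (k in seq_len(nrow(pairs))) {
    i1 <- pairs[k, 1]; i2 <- pairs[k, 2]
    sel <- which(seq_along(wex) %% 2 == (i1 + 1) %% 2)  # wide rows for this pair
    for (wj in wex[sel]) {
      seg <- rbind(c(ufun(i1, wj), wj, 0), c(ufun(i2, wj), wj, 0))
      if (sum((seg[1, ] - seg[2, ])^2) > 1e-18)
        nets[[length(nets) + 1L]] <- beam_network(seg, cbind(1L, 2L), t)
    }
  }
  merge_networks(nets, tol = 1e-9)
}

# map a (u, w) network into the z = 0 plane; swap = TRUE puts w on x
swap_uw <- function(net, swap = FALSE) {
  if (swap) net$vertices <- cbind(net$vertices[, 2], net$vertices[, 1], 0)
  net
}

# normalize a planar network to span exactly [0, width] x [0, height]
normalize_extent <- function(net, width, height) {
  bb <- network_bbox(net)
  for (k in 1:2) {
    span <- bb[2, k] - bb[1, k]
    tgt <- c(width, height)[k]
    if (span > 1e-12)
      net$vertices[, k] <- (net$vertices[, k] - bb[1, k]) * (tgt / span)
  }
  net
}

#' Generate a planar auxetic mesh
#'
#' Constructs the beam network of a planar auxetic topology in the z = 0
#' plane, spanning `[0, width] x [0, height]`.
#'
#' * **re-entrant**: vertical baselines at uniform separation carry corner
#'   vertices whose x positions alternate by `+-amplitude` along the
#'   baseline, with the sign pattern flipped on every consecutive baseline;
#'   corners are chained into vertical zigzags and the facing
#'   positive/negative offset pairs of consecutive baselines are joined by
#'   horizontal beams on alternating rows, producing the bow-tie cell.
#' * **arrowhead**: every baseline carries the same offset pattern; each
#'   negative-offset corner sends two diagonals to the neighboring
#'   positive-offset corners of the next baseline (plus the baseline
#'   zigzags), producing nested arrowheads.
#' * **sinusoidal**: one vertical sinusoid per baseline (period spanning two
#'   horizontal element rows, alternate baselines phase-shifted by half a
#'   period so neighbors are in anti-phase), joined by straight horizontal
#'   connectors at the extreme-offset rows where each pair of neighboring
#'   sinusoids is widest — the curved-wall analogue of the re-entrant
#'   bow-tie.
#' * **pinwheel**: the same construction with zero relative phase shift
#'   between the sinusoids.
#'
#' Sinusoids are discretized into 16 polyline segments per half-period. The
#' finished network is affinely normalized so its bounding box equals the
#' requested extents exactly (as for the printed 10 x 10 mm meshes).
#'
#' @param design a [planar_design()].
#' @return a [beam_network()] (single connected component).
#' @export
gen_planar_auxetic <- function(design) {
  stopifnot(inherits(design, "planar_design"))
  w <- design$width; h <- design$height; A <- design$amplitude
  n1 <- design$n1; n2 <- design$n2
  sepx <- w / max(n1 - 1, 1)
  xpos <- (seq_len(n1) - 1) * sepx
  net <- switch(
    design$kind,
    reentrant = ,
    arrowhead = {
      nr <- 2L * n2
      ypos <- seq(0, h, length.out = nr)
      core <- reentrant_core(xpos, ypos, A, style = design$kind)
      beam_network(cbind(core$uw, 0), core$beams, design$t)
    },
    sinusoidal = ,
    pinwheel = {
      sepy <- h / max(n2 - 1, 1)
      phases <- if (design$kind == "sinusoidal")
        pi * (seq_len(n1) - 1) else rep(0, n1)
      sinusoid_core(xpos, A, 2 * sepy, phases, c(0, h), design$t)
    })
  normalize_extent(net, w, h)
}
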