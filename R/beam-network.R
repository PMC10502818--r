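#' Beam network container
#'
#' The universal lattice representation used throughout the package: a set of
#' 3-D vertices (millimetres) joined by straight beams, each beam carrying the
#' thickness of the solid strut it will be rendered as. Auxetic meshes,
#' cylinders, channel trees and capillary networks are all beam networks.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param beams m x 2 integer matrix of vertex indices (1-based, `a != b`).
#' @param thickness beam thickness (mm); scalar (recycled) or length-m vector.
#' @param labels optional per-beam character tags.
#' @return An object of class `beam_network` with elements `vertices`, `beams`,
#'   `thickness` and `labels`.
#' @examples
#' net <- beam_network(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(1, 2)), 0.2)
#' network_length(net)
#' @export
beam_network <- function(vertices, beams, thickness = 0.3, labels = NULL) {
  vertices <- as_points(vertices)
  beams <- matrix(as.integer(as.matrix(beams)), ncol = 2)
  n <- nrow(vertices)
  if (nrow(beams)) {
    if (any(beams < 1L) || any(beams > n)) stopf("beam indices out of range 1..%d", n)
    if (any(beams[, 1] == beams[, 2])) stopf("degenerate beam: a == b")
    key <- paste(pmin(beams[, 1], beams[, 2]), pmax(beams[, 1], beams[, 2]))
    if (anyDuplicated(key)) stopf("duplicate beams (unordered pairs must be unique)")
  }
  thickness <- rep_len(as.numeric(thickness), nrow(beams))
  if (nrow(beams) && any(thickness <= 0)) stopf("beam thickness must be > 0")
  if (!is.null(labels)) labels <- rep_len(as.character(labels), nrow(beams))
  structure(list(vertices = vertices, beams = beams,
                 thickness = thickness, labels = labels),
            class = "beam_network")
}

#' @export
print.beam_network <- function(x, ...) {
  bb <- network_bbox(x)
  cat(sprintf("beam_network: %d vertices, %d beams\n",
              nrow(x$vertices), nrow(x$beams)))
  cat(sprintf("  thickness: %.3g..%.3g mm; bbox %s mm\n",
              min(x$thickness), max(x$thickness),
              paste(sprintf("%.3g", bb[2, ] - bb[1, ]), collapse = " x ")))
  invisible(x)
}

#' Bounding box of a beam network
#'
#' @param net a [beam_network()].
#' @param inflate add this margin (mm) on every side, e.g. half the beam
#'   thickness to bound the rendered solid rather than the centerlines.
#' @return 2 x 3 matrix: row 1 = minimum corner, row 2 = maximum corner.
#' @export
network_bbox <- function(net, inflate = 0) {
  v <- net$vertices
  rbind(apply(v, 2, min) - inflate, apply(v, 2, max) + inflate)
}

#' Total centerline length of a beam network (mm)
#' @param net a [beam_network()].
#' @export
network_length <- function(net) {
  if (!nrow(net$beams)) return(0)
  a <- net$vertices[net$beams[, 1], , drop = FALSE]
  b <- net$vertices[net$beams[, 2], , drop = FALSE]
  sum(vnorm(b - a))
}

#' Connected components of a beam network
#'
#' Union-find over the beam graph; isolated vertices each form a component.
#' @param net a [beam_network()].
#' @return integer vector of component ids, one per vertex.
#' @export
network_components <- function(net) {
  uf_components(nrow(net$vertices), net$beams)
}

#' Rigid/affine transform of the vertex set
#'
#' Applies `p -> p %*% t(rot) + shift` to every vertex; connectivity and
#' thickness are unchanged.
#' @param net a [beam_network()].
#' @param rot 3 x 3 matrix (default identity).
#' @param shift length-3 translation (mm).
#' @export
transform_network <- function(net, rot = diag(3), shift = c(0, 0, 0)) {
  net$vertices <- net$vertices %*% t(rot) +
    matrix(shift, nrow(net$vertices), 3, byrow = TRUE)
  net
}

#' Merge several beam networks into one
#'
#' Vertices within `tol` of each other are fused; duplicate beams collapse.
#' @param ... beam networks.
#' @param tol vertex merge tolerance (mm).
#' @export
merge_networks <- function(..., tol = 1e-9) {
  nets <- list(...)
  if (length(nets) == 1 && is.list(nets[[1]]) && !inherits(nets[[1]], "beam_network"))
    nets <- nets[[1]]
  verts <- do.call(rbind, lapply(nets, `[[`, "vertices"))
  off <- cumsum(c(0, vapply(nets, function(n) nrow(n$vertices), 1)))
  beams <- do.call(rbind, Map(function(n, o) n$beams + o, nets, off[-length(off)]))
  th <- unlist(lapply(nets, `[[`, "thickness"))
  lab <- lapply(nets, `[[`, "labels")
  lab <- if (all(vapply(lab, is.null, TRUE))) NULL else
    unlist(lapply(seq_along(nets), function(i)
      if (is.null(lab[[i]])) rep(NA_character_, nrow(nets[[i]]$beams)) else lab[[i]]))
  mp <- merge_points(verts, tol)
  beams <- cbind(mp$map[beams[, 1]], mp$map[beams[, 2]])
  keep <- beams[, 1] != beams[, 2]
  beams <- beams[keep, , drop = FALSE]
  th <- th[keep]; if (!is.null(lab)) lab <- lab[keep]
  key <- paste(pmin(beams[, 1], beams[, 2]), pmax(beams[, 1], beams[, 2]))
  first <- !duplicated(key)
  beam_network(mp$vertices, beams[first, , drop = FALSE], th[first],
               if (is.null(lab)) NULL else lab[first])
}

#' Subdivide each beam into k straight segments
#'
#' Interior points are inserted as fresh vertices; thickness is inherited.
#' Used before wrapping/projection so beams follow curved targets.
#' @param net a [beam_network()].
#' @param k segments per beam (scalar or per-beam vector).
#' @export
subdivide_network <- function(net, k) {
  k <- pmax(1L, as.integer(rep_len(k, nrow(net$beams))))
  verts <- list(net$vertices)
  nv <- nrow(net$vertices)
  beams <- vector("list", nrow(net$beams))
  th <- vector("list", nrow(net$beams))
  for (i in seq_len(nrow(net$beams))) {
    a <- net$beams[i, 1]; b <- net$beams[i, 2]; ki <- k[i]
    if (ki == 1L) {
      beams[[i]] <- cbind(a, b); th[[i]] <- net$thickness[i]
      next
    }
    s <- seq_len(ki - 1) / ki
    p <- outer(1 - s, net$vertices[a, ]) + outer(s, net$vertices[b, ])
    ids <- nv + seq_len(ki - 1)
    nv <- nv + ki - 1
    verts[[length(verts) + 1]] <- p
    chain <- c(a, ids, b)
    beams[[i]] <- cbind(chain[-length(chain)], chain[-1])
    th[[i]] <- rep(net$thickness[i], ki)
  }
  beam_network(do.call(rbind, verts), do.call(rbind, beams), unlist(th))
}
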