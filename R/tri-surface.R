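#' Indexed triangle surface
#'
#' Triangle mesh container used for STL I/O, organ-model targets and
#' iso-surface extraction output.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @param drop_degenerate drop zero-area faces instead of erroring.
#' @return An object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces, drop_degenerate = TRUE) {
  vertices <- if (length(vertices)) as_points(vertices) else
    matrix(numeric(0), 0, 3)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (nrow(faces)) {
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stopf("face indices out of range 1..%d", nrow(vertices))
    areas <- face_areas(vertices, faces)
    bad <- areas <= 0
    if (any(bad)) {
      if (!drop_degenerate) stopf("%d degenerate (zero-area) faces", sum(bad))
      faces <- faces[!bad, , drop = FALSE]
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_surface")
}

face_areas <- function(vertices, faces) {
  if (!nrow(faces)) return(numeric(0))
  a <- vertices[faces[, 1], , drop = FALSE]
  u <- vertices[faces[, 2], , drop = FALSE] - a
  v <- vertices[faces[, 3], , drop = FALSE] - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  vnorm(cr) / 2
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("tri_surface: %d vertices, %d faces, area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$faces), surface_area(x)))
  invisible(x)
}

#' Total surface area (mm^2)
#' @param surf a [tri_surface()].
#' @export
surface_area <- function(surf) sum(face_areas(surf$vertices, surf$faces))

#' Euler characteristic V - E + F of a triangle surface
#'
#' Edges are counted as unique unordered vertex pairs; a closed genus-0
#' surface has characteristic 2.
#' @param surf a [tri_surface()].
#' @export
surface_euler <- function(surf) {
  if (!nrow(surf$faces)) return(0L)
  e <- rbind(surf$faces[, c(1, 2)], surf$faces[, c(2, 3)], surf$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  nrow(surf$vertices) - length(unique(key)) + nrow(surf$faces)
}

#' Is every edge shared by exactly two faces?
#' @param surf a [tri_surface()].
#' @export
surface_is_watertight <- function(surf) {
  if (!nrow(surf$faces)) return(FALSE)
  e <- rbind(surf$faces[, c(1, 2)], surf$faces[, c(2, 3)], surf$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# outward (as-stored) unit face normals
face_normals <- function(surf) {
  a <- surf$vertices[surf$faces[, 1], , drop = FALSE]
  u <- surf$vertices[surf$faces[, 2], , drop = FALSE] - a
  v <- surf$vertices[surf$faces[, 3], , drop = FALSE] - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  cr / pmax(vnorm(cr), 1e-300)
}

# tetrahedra decomposition of the cube: corner ids are bit codes
# bx + 2*by + 4*bz; the six tets share the main diagonal 0-7 and tile the
# cube consistently across neighboring cubes (face diagonals match).
mt_tets <- rbind(c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L),
                 c(0L, 2L, 3L, 7L), c(0L, 2L, 6L, 7L),
                 c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L))
# tet edge id -> local tet vertex pair
mt_edges <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                  c(2L, 3L), c(2L, 4L), c(3L, 4L))
# sign pattern (bit i set = tet vertex i inside) -> triangles as edge-id triples
mt_cases <- list(
  `1`  = list(c(1, 2, 3)),
  `2`  = list(c(1, 4, 5)),
  `4`  = list(c(2, 4, 6)),
  `8`  = list(c(3, 5, 6)),
  `14` = list(c(1, 2, 3)),
  `13` = list(c(1, 4, 5)),
  `11` = list(c(2, 4, 6)),
  `7`  = list(c(3, 5, 6)),
  `3`  = list(c(2, 4, 5), c(2, 5, 3)),
  `12` = list(c(2, 4, 5), c(2, 5, 3)),
  `5`  = list(c(1, 4, 6), c(1, 6, 3)),
  `10` = list(c(1, 4, 6), c(1, 6, 3)),
  `9`  = list(c(1, 5, 6), c(1, 6, 2)),
  `6`  = list(c(1, 5, 6), c(1, 6, 2)))

#' Extract an iso-surface from a signed-distance voxel grid
#'
#' Marching tetrahedra over a uniform six-tetrahedron decomposition of each
#' voxel cell. Crossing positions are interpolated linearly along grid edges
#' and computed once per *global* edge, so shared vertices coincide exactly
#' and the mesh is watertight for closed solids away from the grid border.
#' Triangles are oriented with normals pointing towards positive values
#' (outward for the package SDF convention).
#'
#' @param g a [voxel_grid()] holding signed-distance values (3-D shape).
#' @param iso iso level (default 0, the solid boundary).
#' @return a [tri_surface()]; empty (with a warning) when `iso` lies outside
#'   the grid's value range.
#' @export
extract_surface <- function(g, iso = 0) {
  sh <- dim(g$values)
  if (any(sh < 2L))
    stopf("extract_surface needs a 3-D grid (shape >= 2 in every direction)")
  v <- as.vector(g$values)
  if (iso <= min(v) || iso >= max(v)) {
    warnf("iso level %.3g outside value range [%.3g, %.3g]: empty surface",
          iso, min(v), max(v))
    return(tri_surface(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  }
  nx <- sh[1]; ny <- sh[2]; nz <- sh[3]; nxy <- nx * ny
  inside <- v < iso
  corner_off <- c(0L, 1L, nx, nx + 1L, nxy, nxy + 1L, nxy + nx, nxy + nx + 1L)
  # cube bases (corner 000) for all (nx-1)(ny-1)(nz-1) cells
  bi <- seq_len(nx - 1L)
  bj <- seq_len(ny - 1L) - 1L
  bk <- seq_len(nz - 1L) - 1L
  base <- as.vector(outer(outer(bi, bj * nx, `+`), bk * nxy, `+`))
  cnt <- rep(0L, length(base))
  for (o in corner_off) cnt <- cnt + inside[base + o]
  base <- base[cnt > 0L & cnt < 8L]
  if (!length(base))
    return(tri_surface(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))

  nnode <- as.double(length(v))
  node_xyz <- function(id) {
    i0 <- id - 1L
    cbind(g$origin[1] + (i0 %% nx) * g$spacing,
          g$origin[2] + ((i0 %/% nx) %% ny) * g$spacing,
          g$origin[3] + (i0 %/% nxy) * g$spacing)
  }
  tri_g1 <- list(); tri_g2 <- list(); tri_ref <- list(); nt <- 0L
  for (ti in seq_len(nrow(mt_tets))) {
    nid <- vapply(mt_tets[ti, ], function(cid) base + corner_off[cid + 1L],
                  numeric(length(base)))
    nid <- matrix(nid, ncol = 4)
    ins <- matrix(inside[nid], ncol = 4)
    pat <- ins[, 1] + 2L * ins[, 2] + 4L * ins[, 3] + 8L * ins[, 4]
    for (pc in names(mt_cases)) {
      pv <- as.integer(pc)
      rows <- which(pat == pv)
      if (!length(rows)) next
      sub <- nid[rows, , drop = FALSE]
      # reference inside point: centroid of the tet corners below the iso level
      inbits <- which(bitwAnd(pv, c(1L, 2L, 4L, 8L)) > 0L)
      refp_pat <- matrix(0, length(rows), 3)
      for (cc in inbits) refp_pat <- refp_pat + node_xyz(sub[, cc])
      refp_pat <- refp_pat / length(inbits)
      for (tri in mt_cases[[pc]]) {
        nt <- nt + 1L
        uv <- mt_edges[tri, , drop = FALSE]
        tri_g1[[nt]] <- cbind(sub[, uv[1, 1]], sub[, uv[2, 1]], sub[, uv[3, 1]])
        tri_g2[[nt]] <- cbind(sub[, uv[1, 2]], sub[, uv[2, 2]], sub[, uv[3, 2]])
        tri_ref[[nt]] <- refp_pat
      }
    }
  }
  g1 <- do.call(rbind, tri_g1); g2 <- do.call(rbind, tri_g2)
  refp <- do.call(rbind, tri_ref)
  # canonical global edges
  lo <- pmin(g1, g2); hi <- pmax(g1, g2)
  key <- as.vector(lo) + nnode * as.vector(hi)
  ukey <- unique(key)
  vid <- match(key, ukey)
  ulo <- as.vector(lo)[!duplicated(key)]
  uhi <- as.vector(hi)[!duplicated(key)]
  p1 <- node_xyz(ulo); p2 <- node_xyz(uhi)
  t <- (iso - v[ulo]) / (v[uhi] - v[ulo])
  verts <- p1 + t * (p2 - p1)
  faces <- matrix(vid, ncol = 3)
  # orient: normal away from the tet's interior reference point
  a <- verts[faces[, 1], , drop = FALSE]
  u <- verts[faces[, 2], , drop = FALSE] - a
  w <- verts[faces[, 3], , drop = FALSE] - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  centroid <- (a + verts[faces[, 2], , drop = FALSE] +
                 verts[faces[, 3], , drop = FALSE]) / 3
  flip <- rowSums(nrm * (centroid - refp)) < 0
  faces[flip, ] <- faces[flip, c(1, 3, 2)]
  tri_surface(verts, faces)
}
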