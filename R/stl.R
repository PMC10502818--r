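#' Write a triangle surface to STL
#'
#' Binary STL (80-byte header, uint32 triangle count, 50-byte records with
#' float32 normal + vertices) or ASCII STL. Coordinates are stored at
#' float32 precision in both modes.
#'
#' @param surf a [tri_surface()].
#' @param path output file.
#' @param mode `"binary"` (default) or `"ascii"`.
#' @param name solid name embedded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(surf, path, mode = c("binary", "ascii"), name = "auxmesh") {
  mode <- match.arg(mode)
  nf <- nrow(surf$faces)
  v1 <- surf$vertices[surf$faces[, 1], , drop = FALSE]
  v2 <- surf$vertices[surf$faces[, 2], , drop = FALSE]
  v3 <- surf$vertices[surf$faces[, 3], , drop = FALSE]
  nrm <- if (nf) face_normals(surf) else matrix(numeric(0), 0, 3)
  # round-trip through float32 so ASCII and binary writes agree exactly
  f32 <- function(m) {
    con <- rawConnection(raw(0), "wb")
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    out <- rawConnectionValue(con); close(con)
    con <- rawConnection(out, "rb")
    m2 <- matrix(readBin(con, "numeric", length(m), size = 4,
                         endian = "little"), ncol = 3, byrow = TRUE)
    close(con); m2
  }
  v1 <- f32(v1); v2 <- f32(v2); v3 <- f32(v3); nrm <- f32(nrm)
  if (mode == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste("auxmesh binary STL:", name)))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    if (nf) {
      rec <- t(cbind(nrm, v1, v2, v3))  # 12 floats per triangle
      payload <- rawConnection(raw(0), "wb")
      writeBin(as.numeric(rec), payload, size = 4, endian = "little")
      bytes <- rawConnectionValue(payload); close(payload)
      bytes <- matrix(bytes, nrow = 48)
      out <- rbind(bytes, matrix(as.raw(0), 2, nf))  # uint16 attribute = 0
      writeBin(as.vector(out), con)
    }
  } else {
    fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
    lines <- c(sprintf("solid %s", name),
               if (nf) as.vector(rbind(
                 sprintf("  facet normal %s", fmt(nrm)),
                 "    outer loop",
                 sprintf("      vertex %s", fmt(v1)),
                 sprintf("      vertex %s", fmt(v2)),
                 sprintf("      vertex %s", fmt(v3)),
                 "    endloop",
                 "  endfacet")),
               sprintf("endsolid %s", name))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII)
#'
#' The triangle soup is re-indexed: exactly coincident vertices are merged so
#' the result is an indexed [tri_surface()]. Degenerate (zero-area) faces are
#' dropped.
#'
#' @param path STL file path.
#' @return a [tri_surface()].
#' @export
read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz == 0) stopf("%s: empty or unreadable STL file", path)
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", min(sz, 512))
  close(con)
  head_txt <- suppressWarnings(rawToChar(head_raw[head_raw != as.raw(0)]))
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, fixed = TRUE, useBytes = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, sz)
  soup_to_surface(tri)
}

read_stl_binary <- function(path, sz) {
  if (sz < 84) stopf("%s: truncated binary STL (need 84 header bytes, have %d)",
                     path, sz)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  expect <- 84 + 50 * as.double(nf)
  if (nf < 0 || sz != expect)
    stopf("%s: triangle count %d implies %s bytes but file has %d (offset 80)",
          path, nf, format(expect, scientific = FALSE), sz)
  if (nf == 0) return(matrix(numeric(0), 0, 9))
  bytes <- readBin(con, "raw", 50 * nf)
  bytes <- matrix(bytes, nrow = 50)
  fl <- rawConnection(as.vector(bytes[1:48, ]), "rb")
  vals <- readBin(fl, "numeric", 12 * nf, size = 4, endian = "little")
  close(fl)
  vals <- matrix(vals, ncol = 12, byrow = TRUE)
  vals[, 4:12, drop = FALSE]  # drop stored normals, keep 3 vertices
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", lines)
  if (length(vx) %% 3 != 0)
    stopf("%s: ASCII STL vertex count %d is not a multiple of 3 (line %d)",
          path, length(vx), if (length(vx)) vx[length(vx)] else 0)
  if (!length(vx)) return(matrix(numeric(0), 0, 9))
  xyz <- t(vapply(strsplit(trimws(lines[vx]), "\\s+"),
                  function(tok) as.numeric(tok[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stopf("%s: malformed vertex coordinates", path)
  matrix(as.vector(t(xyz)), ncol = 9, byrow = TRUE)
}

# 9-column triangle soup (v1 v2 v3) -> indexed surface, exact-merge vertices
soup_to_surface <- function(tri) {
  if (!nrow(tri)) return(tri_surface(matrix(numeric(0), 0, 3),
                                     matrix(integer(0), 0, 3)))
  pts <- rbind(tri[, 1:3], tri[, 4:6], tri[, 7:9])
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  idx <- match(key, unique(key))
  verts <- pts[!duplicated(idx), , drop = FALSE]
  n <- nrow(tri)
  faces <- cbind(idx[seq_len(n)], idx[n + seq_len(n)], idx[2 * n + seq_len(n)])
  tri_surface(verts, faces)
}
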