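# Independent oracles used across the test files. These deliberately avoid
# the package's own geometry kernels.

vnorm <- function(m) sqrt(rowSums(m * m))

# brute-force point-to-segment distance
oracle_point_segment <- function(p, a, b) {
  ba <- b - a
  bb <- sum(ba * ba)
  h <- if (bb == 0) 0 else max(0, min(1, sum((p - a) * ba) / bb))
  sqrt(sum((p - (a + h * ba))^2))
}

# brute-force point-to-triangle distance by dense constrained search over
# barycentric candidates: interior foot, three edge feet, three corners
oracle_point_triangle <- function(p, a, b, c) {
  cand <- list(a, b, c)
  for (ed in list(list(a, b), list(b, c), list(c, a))) {
    d <- ed[[2]] - ed[[1]]
    t <- sum((p - ed[[1]]) * d) / sum(d * d)
    cand[[length(cand) + 1]] <- ed[[1]] + max(0, min(1, t)) * d
  }
  n <- pracma::cross(b - a, c - a)
  nn <- sum(n * n)
  if (nn > 0) {
    q <- p - n * sum((p - a) * n) / nn
    w <- cbind(b - a, c - a)
    bc <- tryCatch(qr.solve(w, q - a), error = function(e) c(-1, -1))
    if (all(bc > -1e-12) && sum(bc) < 1 + 1e-12)
      cand[[length(cand) + 1]] <- q
  }
  min(vapply(cand, function(x) sqrt(sum((p - x)^2)), numeric(1)))
}

# connected components of a beam graph via igraph (independent of the
# package's union-find)
oracle_n_components <- function(net) {
  g <- igraph::graph_from_edgelist(net$beams, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(net$vertices) - igraph::vcount(g)))
  as.integer(igraph::components(g)$no)
}

# canonical sorted key of a point set, for set-equality comparisons
point_set_key <- function(m, tol = 1e-6) {
  sort(paste(round(m[, 1] / tol), round(m[, 2] / tol), round(m[, 3] / tol)))
}

# canonical triangle-soup key of a surface (orientation-insensitive)
soup_key <- function(surf, digits = 5) {
  v <- surf$vertices
  tri <- lapply(seq_len(nrow(surf$faces)), function(i) {
    m <- v[surf$faces[i, ], , drop = FALSE]
    m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
    paste(round(as.vector(t(m)), digits), collapse = " ")
  })
  sort(unlist(tri))
}
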