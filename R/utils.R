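#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif
#' @importFrom utils modifyList head tail
NULL

# Run code with a private RNG stream; the global .Random.seed is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# coerce x to an n x 3 numeric matrix of coordinates
as_points <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  if (ncol(x) != 3) stopf("points must have 3 columns, got %d", ncol(x))
  if (!all(is.finite(x))) stopf("point coordinates must be finite")
  x
}

vnorm <- function(m) sqrt(rowSums(m * m))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Union-find over n items; pairs is an m x 2 index matrix.
# Returns component id per item (1..k, renumbered).
uf_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# merge coincident points (within tol); returns list(vertices, map old->new)
merge_points <- function(p, tol = 1e-9) {
  key <- paste(round(p[, 1] / tol), round(p[, 2] / tol), round(p[, 3] / tol))
  idx <- match(key, unique(key))
  first <- !duplicated(idx)
  list(vertices = p[first, , drop = FALSE], map = idx)
}
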