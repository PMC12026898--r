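#' Derive a child RNG seed from a base seed and integer keys
#'
#' Streams of randomness inside multi-stage runs (one per CMA-ES child, per
#' restart, per validation evaluation, ...) are derived deterministically from
#' a single user-facing seed, so a whole fit is reproducible from one integer.
#' The result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed Base integer seed.
#' @param ... Further integer keys (epoch, child index, ...), folded in order.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  x <- as.numeric(seed) %% m
  for (k in c(...)) {
    x <- (x * 48271 + as.numeric(k) * 8191 + 1) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

#' Upper-triangular entries of a square matrix in row-major order
#'
#' Returns the strictly-upper-triangular entries ordered row by row,
#' i.e. (1,2), (1,3), ..., (1,N), (2,3), ... This is the fixed entry order
#' used for FC/FCD vectorization throughout the package.
#'
#' @param m A square matrix.
#' @return Numeric vector of length `N(N-1)/2`.
#' @export
upper_triangle <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  # column-major lower triangle enumerates (i,j), j > i, by i then j:
  # exactly the row-major upper triangle of the transposed matrix
  t(m)[lower.tri(m)]
}

# internal: matrix from a row-major upper-triangle vector (symmetric, unit diag)
from_upper_triangle <- function(v, n, diag = 1) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag
  m
}

#' @noRd
assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}
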