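#' Basis-function sets
#'
#' A basis set holds `K` real-valued functions of `x` whose linear
#' combinations model each segment, plus the minimum number of points
#' `lmin` a segment must contain (`lmin >= K` always).
#'
#' @param funcs List of `K` vectorized functions of `x`.
#' @param names Character vector of `K` labels.
#' @param lmin Minimum points per segment; floored at `K`.
#' @return An object of class `"linseg_basis"`.
#' @export
basis_set <- function(funcs, names, lmin) {
  K <- length(funcs)
  stopifnot(K >= 1L, length(names) == K)
  lmin <- as.integer(lmin)
  if (lmin < K) stop("lmin must be at least K = ", K)
  structure(list(K = K, funcs = funcs, names = names, lmin = lmin),
            class = "linseg_basis")
}

#' @export
print.linseg_basis <- function(x, ...) {
  cat(sprintf("<linseg_basis> K = %d {%s}, lmin = %d\n",
              x$K, paste(x$names, collapse = ", "), x$lmin))
  invisible(x)
}

#' Straight-line basis
#'
#' The two functions 1 and x, so each segment is a line with intercept m1
#' and gradient m2.  Three points per segment are required so the residual
#' is informative about a line.
#'
#' @return A [basis_set()] with `K = 2`, `lmin = 3`.
#' @examples
#' b <- make_linear_basis()
#' sapply(b$funcs, function(f) f(2))  # 1, 2
#' @export
make_linear_basis <- function() {
  basis_set(list(function(x) rep(1, length(x)), function(x) x),
            c("1", "x"), lmin = 3L)
}

#' Polynomial basis of a given degree
#'
#' Monomials 1, x, ..., x^degree.  The default `lmin` is `K + 1`, one more
#' point than coefficients, so that residual variance is informative;
#' callers may override down to the floor of `K`.
#'
#' @param degree Polynomial degree, a non-negative integer.
#' @param lmin Minimum points per segment (default `degree + 2`).
#' @return A [basis_set()] with `K = degree + 1`.
#' @export
make_polynomial_basis <- function(degree, lmin = degree + 2L) {
  degree <- as.integer(degree)
  if (is.na(degree) || degree < 0L) stop("degree must be a non-negative integer")
  funcs <- lapply(0:degree, function(p) {
    force(p)
    function(x) x^p
  })
  basis_set(funcs, paste0("x^", 0:degree), lmin = lmin)
}

#' Evaluate the raw (unweighted) basis matrix on a grid
#' @noRd
basis_matrix <- function(basis, x) {
  mat <- vapply(basis$funcs, function(f) as.numeric(f(x)), numeric(length(x)))
  t(matrix(mat, nrow = length(x), ncol = basis$K))  # K x length(x)
}

#' Check linear independence of a basis on a data grid
#'
#' The smallest singular value of the full-grid design matrix must exceed
#' 1e-10 times the largest; otherwise the basis is numerically collinear on
#' this grid and segment matrices would be singular.
#'
#' @param basis A [basis_set()].
#' @param x Numeric grid (the data's x values).
#' @return `TRUE` invisibly; errors when dependent.
#' @export
check_basis_independence <- function(basis, x) {
  if (length(x) < basis$K)
    stop("grid holds fewer points than basis functions")
  sv <- svd(basis_matrix(basis, x), nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 1e-10 * sv[1])
    stop("basis functions are numerically linearly dependent on this grid")
  invisible(TRUE)
}

#' Weighted design matrix of one candidate segment
#'
#' Entry (k, j) is `phi_k(x_j) / sigma_j` over the segment's points; with
#' `N_r` replicates the point columns are tiled `N_r` times (replicates
#' arranged contiguously) to match the flattened observation vector.
#'
#' @param basis A [basis_set()].
#' @param ts A [time_series()].
#' @param i0,i1 Inclusive 1-based segment bounds.
#' @param sigma Per-point error over the segment: a vector of length
#'   `i1 - i0 + 1`, a scalar, or `NULL` for unity (the unknown-error
#'   convention).
#' @return A `K x (N_r * l)` numeric matrix, `l = i1 - i0 + 1`.
#' @export
design_matrix <- function(basis, ts, i0, i1, sigma = NULL) {
  stopifnot(inherits(ts, "linseg_ts"), i0 >= 1L, i1 <= ts$N, i0 <= i1)
  l <- i1 - i0 + 1L
  # the matrix itself only needs K points; the lmin floor is enforced where
  # segments are scored (segment_kernel and the table)
  if (l < basis$K)
    stop("segment [", i0, ", ", i1, "] holds fewer points than basis functions")
  xs <- ts$x[i0:i1]
  if (is.null(sigma)) sigma <- rep(1, l)
  if (length(sigma) == 1L) sigma <- rep(sigma, l)
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  phi <- sweep(basis_matrix(basis, xs), 2L, sigma, "/")
  # replicate-major tiling: columns for replicate 1, then replicate 2, ...
  phi[, rep(seq_len(l), times = ts$N_r), drop = FALSE]
}
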