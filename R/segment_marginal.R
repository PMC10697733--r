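HALF_LOG_2PI <- 0.5 * log(2 * pi)

#' Sufficient statistics of a straight-line segment
#'
#' The six weighted sums from which the linear-segment marginal likelihood
#' follows in closed form:
#' T1 = sum y^2/(2 sigma^2), T2 = sum x^2/(2 sigma^2),
#' T3 = sum 1/(2 sigma^2),  T4 = sum y/sigma^2,
#' T5 = sum x y/sigma^2,    T6 = sum x/sigma^2,
#' with the sums running over the segment's points and over all replicates.
#'
#' @param ts A [time_series()].
#' @param i0,i1 Inclusive 1-based segment bounds.
#' @param sigma Per-point error over the segment (vector of length
#'   `i1 - i0 + 1`, scalar, or `NULL` for unity).
#' @return A named list `T1..T6`.
#' @export
line_suff_stats <- function(ts, i0, i1, sigma = NULL) {
  stopifnot(inherits(ts, "linseg_ts"), i0 >= 1L, i1 <= ts$N, i0 <= i1)
  x <- ts$x[i0:i1]
  y <- ts$y[i0:i1, , drop = FALSE]
  l <- length(x)
  if (is.null(sigma)) sigma <- rep(1, l)
  if (length(sigma) == 1L) sigma <- rep(sigma, l)
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  w <- 1 / sigma^2                      # per-point weight, shared by replicates
  Nr <- ts$N_r
  sy  <- rowSums(y)                     # sum over replicates at each point
  sy2 <- rowSums(y^2)
  list(T1 = sum(w * sy2) / 2,
       T2 = Nr * sum(w * x^2) / 2,
       T3 = Nr * sum(w) / 2,
       T4 = sum(w * sy),
       T5 = sum(w * x * sy),
       T6 = Nr * sum(w * x))
}

#' Gaussian kernel of one candidate segment
#'
#' Decomposes the segment's weighted sum of squares about the basis model
#' into a quadratic form: A = Phi Phi^T (K x K), m_bar the most likely
#' coefficient vector solving `A m_bar = Phi z`, and
#' `2 U = z^T z - m_bar^T A m_bar`, where z is the flattened vector of
#' `y / sigma` over points and replicates.  For the straight-line basis the
#' closed form in the T1..T6 statistics is used; both routes agree to
#' machine precision.
#'
#' @inheritParams line_suff_stats
#' @param basis A [basis_set()].
#' @return An object of class `"linseg_kernel"`: fields `i0`, `i1`, `ell`,
#'   `A`, `m_bar`, `U`, `log_det_A`.
#' @export
segment_kernel <- function(basis, ts, i0, i1, sigma = NULL) {
  l <- i1 - i0 + 1L
  if (l < basis$lmin)
    stop("segment [", i0, ", ", i1, "] shorter than lmin = ", basis$lmin)
  is_line <- basis$K == 2L &&
    identical(basis$names, c("1", "x"))
  if (is_line) {
    tt <- line_suff_stats(ts, i0, i1, sigma)
    det_A <- 4 * tt$T2 * tt$T3 - tt$T6^2
    if (det_A <= 0 || !is.finite(det_A))
      stop("degenerate segment [", i0, ", ", i1, "]: singular normal matrix")
    A <- matrix(c(2 * tt$T3, tt$T6, tt$T6, 2 * tt$T2), 2L, 2L)
    m_bar <- c((2 * tt$T2 * tt$T4 - tt$T5 * tt$T6) / det_A,
               (2 * tt$T3 * tt$T5 - tt$T4 * tt$T6) / det_A)
    U <- tt$T1 - (tt$T2 * tt$T4^2 + tt$T3 * tt$T5^2 -
                    tt$T4 * tt$T5 * tt$T6) / det_A
    log_det_A <- log(det_A)
  } else {
    phi <- design_matrix(basis, ts, i0, i1, sigma)
    sg <- if (is.null(sigma)) rep(1, l) else
      if (length(sigma) == 1L) rep(sigma, l) else sigma
    z <- as.vector(ts$y[i0:i1, , drop = FALSE] / sg)  # replicate-major flatten
    A <- phi %*% t(phi)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    if (ev[length(ev)] <= 0 || ev[1] / ev[length(ev)] > 1e12)
      stop("degenerate segment [", i0, ", ", i1,
           "]: basis collinear on these points")
    ch <- chol(A)
    m_bar <- backsolve(ch, forwardsolve(t(ch), phi %*% z))
    U <- max(0, (sum(z^2) - sum(m_bar * (A %*% m_bar))) / 2)
    m_bar <- as.vector(m_bar)
    log_det_A <- 2 * sum(log(diag(ch)))
  }
  structure(list(i0 = as.integer(i0), i1 = as.integer(i1), ell = l,
                 A = A, m_bar = m_bar, U = max(0, U),
                 log_det_A = log_det_A, K = basis$K, basis = basis),
            class = "linseg_kernel")
}

#' Log marginal likelihood of a segment, known measurement error
#'
#' The Gaussian integral over the coefficients, extended to infinite range
#' (valid when the prior box comfortably contains the likelihood peak; see
#' [check_prior_width()]):
#' `log P(m) - N_r * sum_j log(sqrt(2 pi) sigma_j) + (K/2) log(2 pi)
#'  - log(det A)/2 - U`.
#'
#' @param kernel A [segment_kernel()] built with the same `sigma`.
#' @param prior A [coefficient_prior()].
#' @param ts The [time_series()] (supplies `N_r`).
#' @param sigma Per-point error over the segment (vector, scalar, or `NULL`
#'   for unity), as used for the kernel.
#' @return Scalar log probability.
#' @export
log_marginal_known_sigma <- function(kernel, prior, ts, sigma = NULL) {
  l <- kernel$ell
  if (is.null(sigma)) sigma <- rep(1, l)
  if (length(sigma) == 1L) sigma <- rep(sigma, l)
  prior$log_volume_inv -
    ts$N_r * sum(HALF_LOG_2PI + log(sigma)) +
    kernel$K * HALF_LOG_2PI -
    kernel$log_det_A / 2 -
    kernel$U
}

#' Log marginal likelihood of a segment as a function of a scalar error
#'
#' For the unknown-error path the kernel is built with unit weights and the
#' error enters only through
#' `(-N_r * l + K) * (log(2 pi)/2 + log sigma)` and `-U / sigma^2`.
#'
#' @param kernel A [segment_kernel()] built with unit sigma.
#' @param prior A [coefficient_prior()].
#' @param N_r Replicate count.
#' @param sigma Positive scalar error.
#' @return Scalar log probability.
#' @export
log_marginal_sigma_kernel <- function(kernel, prior, N_r, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  prior$log_volume_inv +
    (-N_r * kernel$ell + kernel$K) * (HALF_LOG_2PI + log(sigma)) -
    kernel$log_det_A / 2 -
    kernel$U / sigma^2
}

#' Prior-width validity check
#'
#' The infinite-range Gaussian integral is a good approximation only when
#' the likelihood peak sits well inside the prior box, i.e. when
#' `sqrt(det A) * P(m) << 1`.  We operationalize "much less than one" as
#' `<= 0.1`.
#'
#' @param kernel A [segment_kernel()].
#' @param prior A [coefficient_prior()].
#' @param quiet Suppress the warning issued when the check fails.
#' @return `TRUE` when the condition holds, else `FALSE` (with a warning
#'   naming the segment unless `quiet`).
#' @export
check_prior_width <- function(kernel, prior, quiet = FALSE) {
  val <- exp(kernel$log_det_A / 2 + prior$log_volume_inv)
  ok <- val <= 0.1
  if (!ok && !quiet)
    warning(sprintf(
      "prior box may be too narrow for segment [%d, %d]: sqrt(det A) * P(m) = %.3g (want <= 0.1)",
      kernel$i0, kernel$i1, val))
  ok
}
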