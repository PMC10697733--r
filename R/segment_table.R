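# Precomputed per-segment quantities for every admissible contiguous
# segment (i0, i1) with i1 - i0 + 1 >= lmin.  For the straight-line basis
# the table is built from cumulative sums of the six sufficient statistics,
# so the whole O(N^2) table costs O(N^2) arithmetic; other bases fall back
# to one kernel factorization per segment.

#' Precompute segment quantities for all admissible segments
#'
#' @param basis A [basis_set()].
#' @param ts A [time_series()].
#' @param prior A [coefficient_prior()].
#' @param sigma_mode `"known"` (use `ts$sigma`, a supplied scalar, or unity)
#'   or `"unknown"` (unit weights; the scalar error is supplied later).
#' @param sigma For `sigma_mode = "known"` only: a scalar error used when
#'   the series carries no `sigma` vector.
#' @return An object of class `"linseg_table"` holding, as `N x N` matrices
#'   indexed `[i0, i1]`: `U`, `log_det_A`, `ell`, and either the full known-
#'   error log marginal `L` or the sigma-independent constant `c0` such that
#'   the unknown-error log marginal is
#'   `c0 + (-N_r*ell + K)*(log(2*pi)/2 + log(sigma)) - U/sigma^2`.
#' @export
precompute_segment_table <- function(basis, ts, prior,
                                     sigma_mode = c("known", "unknown"),
                                     sigma = NULL) {
  sigma_mode <- match.arg(sigma_mode)
  stopifnot(inherits(ts, "linseg_ts"), inherits(prior, "linseg_prior"))
  if (prior$K != basis$K)
    stop("prior has ", prior$K, " coefficient ranges but basis has K = ",
         basis$K)
  N <- ts$N
  lmin <- basis$lmin
  if (N < lmin) stop("series shorter than lmin")
  check_basis_independence(basis, ts$x)

  sig_vec <- NULL
  if (sigma_mode == "known") {
    sig_vec <- if (!is.null(ts$sigma)) ts$sigma
      else if (!is.null(sigma)) rep(as.numeric(sigma), N)
      else rep(1, N)
    if (any(sig_vec <= 0)) stop("sigma must be strictly positive")
  }

  is_line <- basis$K == 2L && identical(basis$names, c("1", "x"))
  tab <- if (is_line) {
    table_linear(ts, prior, sigma_mode, sig_vec, lmin)
  } else {
    table_generic(basis, ts, prior, sigma_mode, sig_vec, lmin)
  }
  tab$basis <- basis
  tab$ts <- ts
  tab$prior <- prior
  tab$sigma_mode <- sigma_mode
  tab$sigma_vec <- sig_vec
  tab$N <- N
  tab$N_r <- ts$N_r
  tab$K <- basis$K
  tab$lmin <- lmin
  tab$is_line <- is_line
  class(tab) <- "linseg_table"
  tab
}

# segment sum of a cumulative vector: seg[a, b] = cs[b + 1] - cs[a]
seg_sums <- function(v) {
  cs <- c(0, cumsum(v))
  N <- length(v)
  outer(-cs[1:N], cs[2:(N + 1)], "+")
}

table_linear <- function(ts, prior, sigma_mode, sig_vec, lmin) {
  N <- ts$N
  Nr <- ts$N_r
  x <- ts$x
  w <- if (is.null(sig_vec)) rep(1, N) else 1 / sig_vec^2
  sy  <- rowSums(ts$y)
  sy2 <- rowSums(ts$y^2)
  T1 <- seg_sums(w * sy2) / 2
  T2 <- Nr * seg_sums(w * x^2) / 2
  T3 <- Nr * seg_sums(w) / 2
  T4 <- seg_sums(w * sy)
  T5 <- seg_sums(w * x * sy)
  T6 <- Nr * seg_sums(w * x)
  detA <- 4 * T2 * T3 - T6^2
  ell <- outer(-(1:N), 1:N, "+") + 1          # ell[a, b] = b - a + 1
  valid <- ell >= lmin
  detA[!valid] <- NA_real_
  m1 <- (2 * T2 * T4 - T5 * T6) / detA
  m2 <- (2 * T3 * T5 - T4 * T6) / detA
  U <- T1 - (T2 * T4^2 + T3 * T5^2 - T4 * T5 * T6) / detA
  U <- pmax(U, 0)                              # guard tiny negative round-off
  U[!valid] <- 0                               # keep log-marginal arithmetic finite
  log_det_A <- log(detA)
  out <- list(U = U, log_det_A = log_det_A, ell = ell,
              m1 = m1, m2 = m2, n_entries = sum(valid))
  if (sigma_mode == "known") {
    cls <- seg_sums(HALF_LOG_2PI + log(sig_vec))
    L <- prior$log_volume_inv - Nr * cls + 2 * HALF_LOG_2PI -
      log_det_A / 2 - U
    L[!valid] <- -Inf
    out$L <- L
  } else {
    c0 <- prior$log_volume_inv - log_det_A / 2
    c0[!valid] <- -Inf
    out$c0 <- c0
  }
  out
}

table_generic <- function(basis, ts, prior, sigma_mode, sig_vec, lmin) {
  N <- ts$N
  U <- matrix(0, N, N)
  log_det_A <- matrix(NA_real_, N, N)
  ell <- outer(-(1:N), 1:N, "+") + 1
  Lc <- matrix(-Inf, N, N)
  n_entries <- 0L
  for (a in 1:(N - lmin + 1L)) {
    for (b in (a + lmin - 1L):N) {
      sg <- if (is.null(sig_vec)) NULL else sig_vec[a:b]
      k <- segment_kernel(basis, ts, a, b, sg)
      U[a, b] <- k$U
      log_det_A[a, b] <- k$log_det_A
      n_entries <- n_entries + 1L
      Lc[a, b] <- if (sigma_mode == "known")
        log_marginal_known_sigma(k, prior, ts, sg)
      else
        prior$log_volume_inv - k$log_det_A / 2
    }
  }
  out <- list(U = U, log_det_A = log_det_A, ell = ell, n_entries = n_entries)
  if (sigma_mode == "known") out$L <- Lc else out$c0 <- Lc
  out
}

#' Fetch one segment kernel from a precomputed table
#'
#' Reconstructs the full [segment_kernel()] of segment `[i0, i1]`.  For the
#' straight-line basis the most likely coefficients come straight from the
#' tabulated statistics; other bases refactorize the segment.
#'
#' @param table A [precompute_segment_table()] result.
#' @param i0,i1 Inclusive 1-based bounds.
#' @return A `"linseg_kernel"` object.
#' @export
get_kernel <- function(table, i0, i1) {
  stopifnot(inherits(table, "linseg_table"))
  if (i1 - i0 + 1L < table$lmin)
    stop("segment [", i0, ", ", i1, "] shorter than lmin")
  sg <- if (is.null(table$sigma_vec)) NULL else table$sigma_vec[i0:i1]
  if (!table$is_line)
    return(segment_kernel(table$basis, table$ts, i0, i1, sg))
  structure(list(i0 = as.integer(i0), i1 = as.integer(i1),
                 ell = i1 - i0 + 1L,
                 A = NULL,
                 m_bar = c(table$m1[i0, i1], table$m2[i0, i1]),
                 U = table$U[i0, i1],
                 log_det_A = table$log_det_A[i0, i1], K = 2L,
                 basis = table$basis),
            class = "linseg_kernel")
}

# Log-marginal matrix at a scalar sigma (unknown-error mode).
table_log_marginals <- function(table, sigma = NULL) {
  if (table$sigma_mode == "known") return(table$L)
  if (is.null(sigma)) stop("sigma required in unknown-error mode")
  table$c0 + (-table$N_r * table$ell + table$K) *
    (HALF_LOG_2PI + log(sigma)) - table$U / sigma^2
}
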