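# Unknown measurement error: the same constant sigma is assumed at every
# point, given a bounded uniform prior, estimated by EM, and marginalized
# numerically.  Every integrand evaluation reuses the unit-weight segment
# kernels: only the sigma-dependent factors of the log marginal change.

#' Default bounds for the unknown-error prior
#'
#' When the coefficient prior carries explicit `sigma_lo`/`sigma_hi` those
#' are used; otherwise the bounds bracket the residual standard deviation
#' `s` of the best single-segment fit: `[max(1e-6, 1e-3 s), 10 s]`.
#'
#' @param table A [precompute_segment_table()] in `"unknown"` mode.
#' @param prior A [coefficient_prior()].
#' @return Length-2 numeric vector `(sigma_lo, sigma_hi)`.
#' @export
default_sigma_bounds <- function(table, prior) {
  if (!is.null(prior$sigma_lo)) return(c(prior$sigma_lo, prior$sigma_hi))
  s <- single_fit_residual_sd(table)
  if (s <= 0)
    stop("data fit the basis perfectly: the error scale is degenerate ",
         "(residual of the single-segment fit is zero); supply sigma bounds")
  c(max(1e-6, 1e-3 * s), 10 * s)
}

single_fit_residual_sd <- function(table) {
  U <- table$U[1L, table$N]
  denom <- table$N_r * table$N - table$K
  sqrt(max(0, 2 * U / denom))
}

#' Estimate the most likely error scale by expectation-maximization
#'
#' For a fixed segment count `M`, iterates
#' `sigma_new^2 = 2 * E[sum_i U_i] / (N_r N - M K)`
#' with the expectation of the summed residual terms taken over the
#' boundary posterior at the current sigma, until the relative change drops
#' below `tol` or `max_iter` iterations.
#'
#' @param table A [precompute_segment_table()] in `"unknown"` mode.
#' @param M Segment count.
#' @param sigma_lo,sigma_hi Bounds of the uniform error prior (see
#'   [default_sigma_bounds()]); the estimate is clamped inside them.
#' @param init_sigma Starting value; default the single-segment residual
#'   standard deviation.
#' @param tol Relative convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A list: `sigma_hat`, `iterations`, `converged`, and `log_scale`
#'   (the log partition sum at `sigma_hat`, used to scale the integrand).
#' @export
em_sigma <- function(table, M, sigma_lo = NULL, sigma_hi = NULL,
                     init_sigma = NULL, tol = 1e-4, max_iter = 100L) {
  stopifnot(inherits(table, "linseg_table"), table$sigma_mode == "unknown")
  denom <- table$N_r * table$N - M * table$K
  if (denom <= 0)
    stop("too few observations for M = ", M, " segments of ", table$K,
         " coefficients")
  if (is.null(sigma_lo)) {
    b <- default_sigma_bounds(table, table$prior)
    sigma_lo <- b[1]; sigma_hi <- b[2]
  }
  s0 <- if (!is.null(init_sigma)) init_sigma else single_fit_residual_sd(table)
  if (s0 <= 0)
    stop("data fit the basis perfectly (all residual terms zero); ",
         "the error scale cannot be estimated")
  sigma_o <- min(max(s0, sigma_lo), sigma_hi)
  converged <- FALSE
  it <- 0L
  ep <- NULL
  while (it < max_iter) {
    it <- it + 1L
    L <- table_log_marginals(table, sigma_o)
    ep <- elim_pass(L, M, Umat = table$U)
    s2 <- 2 * ep$expected_U / denom
    if (!is.finite(s2) || s2 <= 0)
      stop("degenerate EM update: expected residual is zero ",
           "(data lie exactly on the basis span)")
    sigma_n <- min(max(sqrt(s2), sigma_lo), sigma_hi)
    if (abs(sigma_n - sigma_o) / sigma_o < tol) {
      sigma_o <- sigma_n
      converged <- TRUE
      break
    }
    sigma_o <- sigma_n
  }
  log_scale <- elim_pass(table_log_marginals(table, sigma_o), M)$log_sum
  list(sigma_hat = sigma_o, iterations = it, converged = converged,
       log_scale = log_scale)
}

# Vector-valued adaptive Simpson quadrature.  f maps a scalar to a numeric
# vector; the interval is split until the Richardson error estimate of
# every component is below rtol * |integral| (or atol), subject to a cap on
# integrand evaluations.  Deterministic by construction.
adaptive_simpson <- function(f, a, b, rtol = 1e-6, atol = 1e-12,
                             max_evals = 200L) {
  evals <- 0L
  fv <- function(x) { evals <<- evals + 1L; f(x) }
  fa <- fv(a); fb <- fv(b); fm <- fv((a + b) / 2)
  simp <- function(h, f1, f2, f3) h / 6 * (f1 + 4 * f2 + f3)
  rec <- function(a, b, fa, fm, fb, whole, depth) {
    m <- (a + b) / 2
    flm <- fv((a + m) / 2); frm <- fv((m + b) / 2)
    left <- simp(m - a, fa, flm, fm)
    right <- simp(b - m, fm, frm, fb)
    err <- (left + right - whole) / 15
    tolv <- pmax(atol, rtol * abs(left + right))
    if (depth <= 0L || evals >= max_evals || all(abs(err) <= tolv))
      return(left + right + err)
    rec(a, m, fa, flm, fm, left, depth - 1L) +
      rec(m, b, fm, frm, fb, right, depth - 1L)
  }
  res <- rec(a, b, fa, fm, fb, simp(b - a, fa, fm, fb), 20L)
  attr(res, "evals") <- evals
  res
}

# Integrate a sharply peaked integrand by splitting the interval at anchor
# points around the peak (the EM estimate), so the adaptive rule cannot
# step over the mass.  `width` is the estimated scale of the peak.
integrate_peaked <- function(f, lo, hi, center, width, rtol = 1e-6,
                             max_evals = 200L) {
  anchors <- c(lo, center + width * c(-50, -20, -5, 0, 5, 20, 50), hi)
  anchors <- sort(unique(pmin(hi, pmax(lo, anchors))))
  total <- NULL
  budget <- max(20L, max_evals %/% (length(anchors) - 1L))
  for (i in seq_len(length(anchors) - 1L)) {
    piece <- adaptive_simpson(f, anchors[i], anchors[i + 1L], rtol = rtol,
                              max_evals = budget)
    total <- if (is.null(total)) as.numeric(piece)
      else total + as.numeric(piece)
  }
  total
}

#' Log evidence for M segments, unknown measurement error
#'
#' Numerically integrates the partition sum over the error scale on
#' `[sigma_lo, sigma_hi]`, each integrand evaluation being one full
#' variable-elimination pass at that sigma.  To prevent overflow the
#' integrand is scaled by its value at the EM estimate of sigma (the log of
#' that value is added back), and the constant error prior
#' `1/(sigma_hi - sigma_lo)` is included so values are comparable across
#' `M` at fixed bounds.
#'
#' @inheritParams em_sigma
#' @param rtol Quadrature relative tolerance.
#' @param max_evals Cap on integrand evaluations.
#' @return Scalar log evidence (`-Inf` when `M` is infeasible).
#' @export
log_evidence_unknown_sigma <- function(table, M, sigma_lo = NULL,
                                       sigma_hi = NULL, rtol = 1e-6,
                                       max_evals = 200L) {
  stopifnot(inherits(table, "linseg_table"), table$sigma_mode == "unknown")
  if (table$N < M * table$lmin) return(-Inf)
  if (is.null(sigma_lo)) {
    b <- default_sigma_bounds(table, table$prior)
    sigma_lo <- b[1]; sigma_hi <- b[2]
  }
  em <- em_sigma(table, M, sigma_lo, sigma_hi)
  S_hat <- em$log_scale
  f <- function(s)
    exp(elim_pass(table_log_marginals(table, s), M)$log_sum - S_hat)
  w <- em$sigma_hat / sqrt(2 * (table$N_r * table$N - M * table$K))
  I <- integrate_peaked(f, sigma_lo, sigma_hi, em$sigma_hat, w,
                        rtol = rtol, max_evals = max_evals)
  log_prior_boundaries(table$N, M, table$lmin) -
    log(sigma_hi - sigma_lo) + S_hat + log(I)
}

#' Posterior boundary moments, unknown measurement error
#'
#' Means and variances of the interior boundaries marginalized over the
#' error scale with the same scaled quadrature as
#' [log_evidence_unknown_sigma()]: each sigma evaluation yields the
#' conditional normalization and conditional first two boundary moments,
#' and the vector-valued integral is assembled into marginal moments.
#'
#' @inheritParams log_evidence_unknown_sigma
#' @return A list with numeric vectors `mean` and `var` of length `M - 1`.
#' @export
posterior_boundaries_unknown_sigma <- function(table, M, sigma_lo = NULL,
                                               sigma_hi = NULL, rtol = 1e-6,
                                               max_evals = 200L) {
  stopifnot(inherits(table, "linseg_table"), table$sigma_mode == "unknown")
  if (M < 2L) return(list(mean = numeric(0), var = numeric(0)))
  if (table$N < M * table$lmin) stop("M = ", M, " infeasible")
  if (is.null(sigma_lo)) {
    b <- default_sigma_bounds(table, table$prior)
    sigma_lo <- b[1]; sigma_hi <- b[2]
  }
  em <- em_sigma(table, M, sigma_lo, sigma_hi)
  S_hat <- em$log_scale
  f <- function(s) {
    ep <- elim_pass(table_log_marginals(table, s), M, want_moments = TRUE)
    z <- exp(ep$log_sum - S_hat)
    c(z, z * ep$mean, z * (ep$var + ep$mean^2))
  }
  w <- em$sigma_hat / sqrt(2 * (table$N_r * table$N - M * table$K))
  I <- integrate_peaked(f, sigma_lo, sigma_hi, em$sigma_hat, w,
                        rtol = rtol, max_evals = max_evals)
  z <- I[1L]
  m1 <- I[1L + seq_len(M - 1L)] / z
  m2 <- I[M + seq_len(M - 1L)] / z
  list(mean = m1, var = pmax(m2 - m1^2, 0))
}
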