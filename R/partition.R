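# Evidence per segment count by variable elimination, model selection, and
# posterior boundary moments.
#
# Boundary convention (1-based): with M segments there are M - 1 interior
# boundaries n = (n_1, ..., n_{M-1}); n_i is the index of the LAST point of
# segment i, so segments are [1, n_1], [n_1 + 1, n_2], ..., [n_{M-1} + 1, N]
# and the spacing constraints are n_1 >= lmin, n_{i+1} >= n_i + lmin,
# n_{M-1} <= N - lmin.

row_lse <- function(W) {
  m <- W[cbind(seq_len(nrow(W)), max.col(W, ties.method = "first"))]
  out <- m + log(rowSums(exp(W - m)))
  out[!is.finite(m)] <- -Inf
  out
}

lse <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

#' Number of admissible boundary configurations
#'
#' Counts the boundary vectors that cut `N` points into `M` contiguous
#' segments of at least `lmin` points each, by the same elimination
#' recursion used for the evidence (the closed form is
#' `choose(N - M*lmin + M - 1, M - 1)`; the two agree and the closed form
#' serves as an independent oracle in the tests).
#'
#' @param N Point count.
#' @param M Segment count, `>= 1`.
#' @param lmin Minimum points per segment.
#' @return The count (0 when `N < M * lmin`, i.e. infeasible).
#' @export
count_valid_partitions <- function(N, M, lmin) {
  stopifnot(M >= 1, lmin >= 1)
  if (N < M * lmin) return(0)
  if (M == 1) return(1)
  # g[j] = number of ways to cover points j..N with m segments
  g <- rep(0, N + 1L)
  g[seq_len(N + 1L - lmin)] <- 1         # m = 1: any j with N - j + 1 >= lmin
  for (m in 2:M) {
    gn <- rep(0, N + 1L)
    # first segment [j, b] with b - j + 1 >= lmin, remainder covered by m-1
    rc <- rev(cumsum(rev(g)))            # rc[t] = sum_{u >= t} g[u]
    for (j in seq_len(N + 1L - m * lmin))
      gn[j] <- rc[j + lmin]              # sum over b + 1 = j + lmin .. N + 1
    g <- gn
  }
  g[1L]
}

#' Log prior of a boundary configuration
#'
#' All admissible configurations are equally likely, so the log prior is
#' minus the log count; computed with `lchoose` for stability at large `N`.
#'
#' @inheritParams count_valid_partitions
#' @return Scalar log probability (`-Inf` when infeasible).
#' @export
log_prior_boundaries <- function(N, M, lmin) {
  stopifnot(M >= 1, lmin >= 1)
  if (N < M * lmin) return(-Inf)
  -lchoose(N - M * lmin + M - 1, M - 1)
}

# Backward sweep: G[[m]][j] = log sum over partitions of points j..N into m
# segments of the product of segment marginals.  L is the N x N
# log-marginal matrix (rows i0, cols i1; -Inf where inadmissible).
elim_backward <- function(L, M) {
  N <- nrow(L)
  G <- vector("list", M)
  G[[1L]] <- L[, N]
  if (M >= 2L) {
    for (m in 2:M) {
      gs <- c(G[[m - 1L]][-1L], -Inf)          # gs[b] = G_{m-1}(b + 1)
      G[[m]] <- row_lse(L + matrix(gs, N, N, byrow = TRUE))
    }
  }
  G
}

# Forward sweep: F[[m]][b] = log sum over ways the first m segments cover
# points 1..b.
elim_forward <- function(L, M) {
  N <- nrow(L)
  F <- vector("list", M)
  F[[1L]] <- L[1L, ]
  if (M >= 2L) {
    for (m in 2:M) {
      fp <- F[[m - 1L]]
      # F_m(b) = LSE_a fp(a) + L[a + 1, b]
      W <- L[-1L, , drop = FALSE] + fp[-N]
      F[[m]] <- row_lse(t(W))
    }
  }
  F
}

# Core sums for one M at a fixed log-marginal matrix L.  Returns the log
# partition sum (log sum_n prod_i P(D_i)), and optionally boundary moments
# and the posterior expectation of the summed residual terms E[sum_i U_i]
# (needed by the EM update for unknown error).
elim_pass <- function(L, M, want_moments = FALSE, Umat = NULL) {
  N <- nrow(L)
  G <- elim_backward(L, M)
  S <- G[[M]][1L]
  out <- list(log_sum = S)
  if (!want_moments && is.null(Umat)) return(out)
  F <- elim_forward(L, M)
  if (want_moments && M >= 2L) {
    idx <- seq_len(N - 1L)
    m1 <- numeric(M - 1L); m2 <- numeric(M - 1L)
    for (i in seq_len(M - 1L)) {
      lp <- F[[i]][idx] + G[[M - i]][idx + 1L] - S
      p <- exp(lp)
      p[!is.finite(lp)] <- 0
      m1[i] <- sum(idx * p)
      m2[i] <- sum(idx^2 * p)
    }
    out$mean <- m1
    out$var <- pmax(m2 - m1^2, 0)
  }
  if (!is.null(Umat)) {
    eu <- 0
    for (s in seq_len(M)) {
      lf <- if (s == 1L) c(0, rep(-Inf, N - 1L)) else c(-Inf, F[[s - 1L]][-N])
      lg <- if (s == M) c(rep(-Inf, N - 1L), 0) else c(G[[M - s]][-1L], -Inf)
      lw <- outer(lf, lg, "+") + L - S
      pw <- exp(lw)
      pw[!is.finite(lw)] <- 0
      eu <- eu + sum(pw * Umat)
    }
    out$expected_U <- eu
  }
  out
}

#' Log evidence for M segments, known measurement error
#'
#' Sums the product of segment marginal likelihoods over every admissible
#' boundary configuration by variable elimination (eliminating the last
#' boundary first), in `O(M N^2)` log-sum-exp operations, and adds the log
#' boundary prior.
#'
#' @param table A [precompute_segment_table()] in `"known"` mode.
#' @param M Segment count.
#' @return Scalar log evidence (`-Inf` when `M` is infeasible).
#' @export
log_evidence_known_sigma <- function(table, M) {
  stopifnot(inherits(table, "linseg_table"), table$sigma_mode == "known")
  if (table$N < M * table$lmin) return(-Inf)
  log_prior_boundaries(table$N, M, table$lmin) +
    elim_pass(table$L, M)$log_sum
}

#' Select the evidence-optimal number of segments
#'
#' Argmax of the log evidence; exact ties go to the smaller M (the evidence
#' already penalizes complexity, and parsimony breaks what it cannot).
#'
#' @param log_evidence Numeric vector of log evidences.
#' @param M_values The segment counts they correspond to (default
#'   `seq_along(log_evidence)`).
#' @return The selected segment count.
#' @export
select_M <- function(log_evidence, M_values = seq_along(log_evidence)) {
  keep <- is.finite(log_evidence)
  if (!any(keep)) stop("no feasible M was evaluated")
  le <- log_evidence[keep]; mv <- M_values[keep]
  mv[order(-le, mv)][1L]
}

#' Posterior mean and variance of each boundary, known measurement error
#'
#' First two moments of each interior boundary index under the boundary
#' posterior for a fixed `M`, computed with the same elimination schedule
#' as the evidence (one forward and one backward sweep).
#'
#' @inheritParams log_evidence_known_sigma
#' @return A list with numeric vectors `mean` and `var` of length `M - 1`
#'   (empty for `M = 1`).
#' @export
posterior_boundary_moments <- function(table, M) {
  stopifnot(inherits(table, "linseg_table"), table$sigma_mode == "known")
  if (M < 2L) return(list(mean = numeric(0), var = numeric(0)))
  if (table$N < M * table$lmin) stop("M = ", M, " infeasible for N = ", table$N)
  ep <- elim_pass(table$L, M, want_moments = TRUE)
  list(mean = ep$mean, var = ep$var)
}

# Round posterior boundary means to the admissible integer configuration
# minimizing total absolute displacement (small DP over boundary values).
round_boundaries <- function(means, N, lmin) {
  M1 <- length(means)
  if (!M1) return(integer(0))
  M <- M1 + 1L
  lo <- lmin * seq_len(M1)
  hi <- N - lmin * (M - seq_len(M1))
  cost <- abs(seq_len(N) - means[1L])
  cost[seq_len(N) < lo[1L] | seq_len(N) > hi[1L]] <- Inf
  choice <- matrix(0L, M1, N)
  if (M1 >= 2L) {
    for (i in 2:M1) {
      # best predecessor with n_{i-1} <= v - lmin
      run_min <- cummin(cost)
      run_arg <- integer(N); best <- Inf
      for (v in seq_len(N)) {
        if (cost[v] < best) { best <- cost[v]; run_arg[v] <- v }
        else run_arg[v] <- if (v > 1L) run_arg[v - 1L] else 0L
      }
      nc <- rep(Inf, N)
      for (v in seq_len(N)) {
        if (v < lo[i] || v > hi[i] || v - lmin < 1L) next
        pm <- run_min[v - lmin]
        if (is.finite(pm)) {
          nc[v] <- abs(v - means[i]) + pm
          choice[i, v] <- run_arg[v - lmin]
        }
      }
      cost <- nc
    }
  }
  end <- which.min(cost)
  if (!is.finite(cost[end])) stop("no admissible integer boundary configuration")
  out <- integer(M1)
  out[M1] <- end
  if (M1 >= 2L) for (i in M1:2) out[i - 1L] <- choice[i, out[i]]
  out
}

#' Partition a series into its evidence-optimal segments
#'
#' The top-level analysis: evaluates the log evidence for each candidate
#' segment count `M = 1..M_max` (known- or unknown-error path), selects the
#' optimal `M`, computes posterior boundary means and variances, rounds the
#' means to the nearest admissible integer configuration, and attaches
#' per-segment fit statistics.
#'
#' @param ts A [time_series()].
#' @param prior A [coefficient_prior()] (see [build_coefficient_prior()]
#'   for the straight-line shortcuts).
#' @param basis A [basis_set()]; default straight lines.
#' @param sigma Error specification: `"unknown"` (default when the series
#'   carries no error column), a positive scalar, or `NULL` to use the
#'   series' own `sigma` column.
#' @param M_max Largest segment count to evaluate; trimmed to
#'   `floor(N / lmin)` and defaulting to `min(10, floor(N / lmin))`.
#' @param quiet Suppress prior-width warnings for the selected segments.
#' @return An object of class `"linseg_partition"`: fields `M_values`,
#'   `log_evidence`, `M_best`, `boundaries_mean`, `boundaries_var`,
#'   `boundaries_index`, `segments` (two-column matrix of inclusive 1-based
#'   bounds), `stats` (list of per-segment [segment_stats()]), `sigma_mode`,
#'   `sigma_hat` (unknown-error mode), and `table`.
#' @examples
#' x <- 0:29
#' y <- c(0.5 * x[1:15], 7.5 - 0.5 * (x[16:30] - 14.5))
#' ts <- time_series(x, y + rnorm(30, 0, 0.1))
#' fit <- partition(ts, coefficient_prior(c(-20, -5), c(20, 5)), sigma = 0.1)
#' fit$M_best
#' @export
partition <- function(ts, prior, basis = make_linear_basis(),
                      sigma = "unknown", M_max = NULL, quiet = FALSE) {
  stopifnot(inherits(ts, "linseg_ts"))
  unknown <- identical(sigma, "unknown")
  lmin <- basis$lmin
  feas_max <- floor(ts$N / lmin)
  if (feas_max < 1L) stop("series shorter than lmin = ", lmin)
  if (is.null(M_max)) M_max <- min(10L, feas_max)
  if (ts$N < 2L * lmin && M_max > 1L)
    warning("fewer than 2*lmin points: only M = 1 can be assessed")
  if (M_max > feas_max) M_max <- feas_max
  M_values <- seq_len(M_max)

  if (unknown) {
    table <- precompute_segment_table(basis, ts, prior, "unknown")
    bounds <- default_sigma_bounds(table, prior)
    ev <- vapply(M_values, function(M)
      log_evidence_unknown_sigma(table, M, sigma_lo = bounds[1],
                                 sigma_hi = bounds[2]), numeric(1))
    M_best <- select_M(ev, M_values)
    em <- em_sigma(table, M_best, sigma_lo = bounds[1], sigma_hi = bounds[2])
    mom <- posterior_boundaries_unknown_sigma(table, M_best,
                                              sigma_lo = bounds[1],
                                              sigma_hi = bounds[2])
    sigma_hat <- em$sigma_hat
  } else {
    sig_scalar <- if (is.null(sigma)) NULL else as.numeric(sigma)
    table <- precompute_segment_table(basis, ts, prior, "known",
                                      sigma = sig_scalar)
    ev <- vapply(M_values, function(M) log_evidence_known_sigma(table, M),
                 numeric(1))
    M_best <- select_M(ev, M_values)
    mom <- posterior_boundary_moments(table, M_best)
    sigma_hat <- NULL
  }

  bidx <- round_boundaries(mom$mean, ts$N, lmin)
  starts <- c(1L, bidx + 1L)
  ends <- c(bidx, ts$N)
  segments <- cbind(start = starts, end = ends)
  stats <- lapply(seq_len(M_best), function(i) {
    k <- get_kernel(table, starts[i], ends[i])
    if (!quiet) {
      kc <- k
      if (unknown && !is.null(sigma_hat))  # det A scales as sigma^(-2K)
        kc$log_det_A <- k$log_det_A - 2 * k$K * log(sigma_hat)
      check_prior_width(kc, prior)
    }
    segment_stats(k, ts)
  })

  structure(list(M_values = M_values, log_evidence = ev, M_best = M_best,
                 boundaries_mean = mom$mean, boundaries_var = mom$var,
                 boundaries_index = bidx, segments = segments,
                 stats = stats, sigma_mode = if (unknown) "unknown" else "known",
                 sigma_hat = sigma_hat, table = table),
            class = "linseg_partition")
}

#' @export
print.linseg_partition <- function(x, ...) {
  cat(sprintf("<linseg_partition> M_best = %d (of %d evaluated), %s error\n",
              x$M_best, length(x$M_values), x$sigma_mode))
  cat("  log evidence:",
      paste(sprintf("M=%d: %.2f", x$M_values, x$log_evidence),
            collapse = ", "), "\n")
  if (length(x$boundaries_mean))
    cat("  boundaries (posterior mean +/- sd):",
        paste(sprintf("%.2f +/- %.2f", x$boundaries_mean,
                      sqrt(x$boundaries_var)), collapse = ", "), "\n")
  for (i in seq_len(x$M_best)) {
    s <- x$stats[[i]]
    if (!is.null(s$gradient))
      cat(sprintf("  segment %d [%d, %d]: gradient %.4g, intercept %.4g, R2 %.4f\n",
                  i, s$start, s$end, s$gradient, s$intercept, s$r_squared))
    else
      cat(sprintf("  segment %d [%d, %d]: R2 %.4f\n",
                  i, s$start, s$end, s$r_squared))
  }
  invisible(x)
}
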