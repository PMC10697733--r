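# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: enumeration instead of elimination,
# dense quadrature instead of closed forms, textbook least squares instead
# of the sufficient-statistic algebra.

# All admissible boundary vectors (n_1, ..., n_{M-1}) as a matrix row-wise;
# a 0-column matrix with one row for M = 1.
enum_boundaries <- function(N, M, lmin) {
  if (M == 1) return(matrix(integer(0), nrow = 1))
  rec <- function(prev, left) {
    lo <- prev + lmin
    hi <- N - left * lmin
    if (lo > hi) return(NULL)
    out <- list()
    for (v in lo:hi) {
      if (left == 1) out[[length(out) + 1]] <- v
      else {
        sub <- rec(v, left - 1)
        if (!is.null(sub)) out[[length(out) + 1]] <- cbind(v, sub)
      }
    }
    if (!length(out)) return(NULL)
    do.call(rbind, lapply(out, rbind))
  }
  m <- rec(0, M - 1)
  matrix(as.integer(m), ncol = M - 1)
}

lse0 <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

# Segment bounds implied by a boundary vector.
bounds_from_n <- function(n, N) {
  starts <- c(1L, n + 1L)
  ends <- c(n, N)
  cbind(starts, ends)
}

# Brute-force log sum over all boundary vectors of the product of segment
# marginals, given the N x N log-marginal matrix L.
brute_log_sum <- function(L, N, M, lmin) {
  nb <- enum_boundaries(N, M, lmin)
  terms <- apply(nb, 1, function(n) {
    b <- bounds_from_n(as.integer(n), N)
    sum(L[cbind(b[, 1], b[, 2])])
  })
  if (!length(terms)) terms <- {  # M = 1: single segment
    L[1, N]
  }
  lse0(terms)
}

# Brute-force posterior boundary moments from the same enumeration.
brute_moments <- function(L, N, M, lmin) {
  nb <- enum_boundaries(N, M, lmin)
  lw <- apply(nb, 1, function(n) {
    b <- bounds_from_n(as.integer(n), N)
    sum(L[cbind(b[, 1], b[, 2])])
  })
  w <- exp(lw - lse0(lw))
  list(mean = colSums(nb * w), var = colSums(nb^2 * w) - colSums(nb * w)^2,
       total = sum(w))
}

# Dense 2-D trapezoid quadrature of the known-error segment integrand
# (straight-line basis): P(m) * prod_j (2 pi sigma_j^2)^(-Nr/2) *
# exp(-sum_{j,r} (y - m1 - m2 x)^2 / (2 sigma_j^2)), on a grid centred on
# the weighted least-squares solution and wide enough to hold the mass.
quad_log_marginal_line <- function(ts, i0, i1, sigma, prior, ngrid = 401) {
  x <- ts$x[i0:i1]
  y <- ts$y[i0:i1, , drop = FALSE]
  l <- length(x)
  if (length(sigma) == 1) sigma <- rep(sigma, l)
  X <- cbind(1, x)
  # weighted LS on pooled replicates
  Xr <- X[rep(seq_len(l), ts$N_r), ]
  yr <- as.vector(y)
  wr <- rep(1 / sigma^2, ts$N_r)
  cf <- lm.fit(Xr * sqrt(wr), yr * sqrt(wr))$coefficients
  # curvature-based grid half-widths
  A <- t(Xr * wr) %*% Xr
  sd1 <- sqrt(solve(A)[1, 1]); sd2 <- sqrt(solve(A)[2, 2])
  m1g <- seq(cf[1] - 10 * sd1, cf[1] + 10 * sd1, length.out = ngrid)
  m2g <- seq(cf[2] - 10 * sd2, cf[2] + 10 * sd2, length.out = ngrid)
  loglik <- function(m1, m2) {
    pred <- m1 + m2 * x
    -sum((y - pred)^2 / (2 * sigma^2))
  }
  lmat <- outer(seq_along(m1g), seq_along(m2g),
                Vectorize(function(i, j) loglik(m1g[i], m2g[j])))
  # trapezoid weights
  wt1 <- rep(1, ngrid); wt1[c(1, ngrid)] <- 0.5
  wt2 <- wt1
  mx <- max(lmat)
  I <- sum(exp(lmat - mx) * outer(wt1, wt2)) * diff(m1g[1:2]) * diff(m2g[1:2])
  prior$log_volume_inv - ts$N_r * sum(0.5 * log(2 * pi) + log(sigma)) +
    mx + log(I)
}

# Random multi-segment test series.
random_ts <- function(N, N_r = 1, sigma = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- sort(runif(N, 0, 10))
  y <- matrix(rnorm(N * N_r, sin(x), 1), N, N_r)
  time_series(x, y, sigma = sigma)
}

# A noiseless V shape: slope -1 then +1 with the corner at point `corner`.
vshape_ts <- function(N = 30, corner = 15, N_r = 1, noise = 0, seed = 1) {
  set.seed(seed)
  x <- seq_len(N)
  f <- abs(x - corner)
  time_series(x, matrix(f + rnorm(N * N_r, 0, noise), N, N_r))
}

wide_prior <- function(lo = -100, hi = 100)
  coefficient_prior(c(lo, lo), c(hi, hi))
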