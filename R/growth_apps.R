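# Applications to microbial growth: linear range of OD calibration curves,
# automatic log-phase detection, and Monod-equation fitting.

#' Linear range of an OD calibration curve
#'
#' Calibration data relate the optical density of serial dilutions of a
#' dense culture to the dilution factor (relative cell number).  OD is
#' proportional to cell number only at low density, so the curve is linear
#' only up to some OD.  This partitions OD vs dilution factor with the
#' straight-line basis and unknown measurement error; the linear range is
#' the segment beginning at the smallest OD, and the ratio of its maximal
#' OD to the matching dilution factor converts dilution factors back to ODs.
#'
#' @param ts A [time_series()]: `x` = dilution factor (ascending), `y` = OD
#'   replicates.
#' @param prior A [coefficient_prior()]; with OD data,
#'   `build_coefficient_prior(ts, y_range = c(0, 2))` is a natural choice.
#' @param M_max Passed to [partition()].
#' @param quiet Passed to [partition()].
#' @return A list: `partition` (the full [partition()] result), `segments`
#'   (per-segment stats), `linear_segment` (smallest-OD segment),
#'   `highest_r2_segment`, `od_max` (replicate-mean OD at the linear
#'   segment's upper end), `dilution_at_od_max`, and `scale_factor`
#'   (`od_max / dilution_at_od_max`).
#' @export
od_linear_range <- function(ts, prior, M_max = NULL, quiet = FALSE) {
  stopifnot(inherits(ts, "linseg_ts"))
  fit <- partition(ts, prior, sigma = "unknown", M_max = M_max, quiet = quiet)
  segs <- fit$stats
  linear <- segs[[1L]]                      # segment beginning at smallest OD
  best_r2 <- select_segment(segs, "r2")
  if (fit$M_best == 1L && !quiet)
    message("whole range is linear (M_best = 1); scale factor taken from ",
            "the last point")
  end <- linear$end
  od_max <- mean(ts$y[end, ])
  dil <- ts$x[end]
  list(partition = fit, segments = segs, linear_segment = linear,
       highest_r2_segment = best_r2, od_max = od_max,
       dilution_at_od_max = dil,
       scale_factor = od_max / dil)
}

#' Detect the exponential (log) phase of a growth curve
#'
#' Takes the natural log of the OD replicates, partitions log(OD) vs time
#' with the straight-line basis and unknown measurement error, and selects
#' the segment whose best-fit line has the largest gradient: in log phase
#' the log of cell number grows linearly, and the greatest gradient is the
#' greatest specific growth rate.
#'
#' @param ts A [time_series()]: `x` = time (hours), `y` = OD replicates,
#'   all strictly positive.
#' @param prior A [coefficient_prior()] for the (intercept, gradient) of
#'   log(OD) vs time; e.g.
#'   `build_coefficient_prior(log_ts, gradient_range = c(0, 5))` for
#'   rates up to 5 per hour.  May also be a function of the logged series,
#'   called as `prior(log_ts)`, convenient because the prior box depends on
#'   the transformed data.
#' @param M_max Passed to [partition()].
#' @param quiet Passed to [partition()].
#' @return A list of class `"linseg_logphase"`: `partition`, `segments`,
#'   `log_phase` (the selected segment), `specific_growth_rate` (its
#'   gradient, in inverse time units), `boundaries_mean`, `boundaries_var`.
#' @export
find_log_phase <- function(ts, prior, M_max = NULL, quiet = FALSE) {
  stopifnot(inherits(ts, "linseg_ts"))
  bad <- which(apply(ts$y <= 0, 1L, any))
  if (length(bad))
    stop("OD must be positive to take logs; offending row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  log_ts <- time_series(ts$x, log(ts$y), sigma = ts$sigma)
  if (is.function(prior)) prior <- prior(log_ts)
  fit <- partition(log_ts, prior, sigma = "unknown", M_max = M_max,
                   quiet = quiet)
  sel <- select_segment(fit$stats, "gradient")
  structure(list(partition = fit, segments = fit$stats, log_phase = sel,
                 specific_growth_rate = sel$gradient,
                 boundaries_mean = fit$boundaries_mean,
                 boundaries_var = fit$boundaries_var),
            class = "linseg_logphase")
}

#' @export
print.linseg_logphase <- function(x, ...) {
  cat(sprintf("<linseg_logphase> %d segment(s); log phase = segment %d [%d, %d]\n",
              x$partition$M_best, attr(x$log_phase, "which"),
              x$log_phase$start, x$log_phase$end))
  cat(sprintf("  specific growth rate: %.4g per time unit\n",
              x$specific_growth_rate))
  invisible(x)
}

#' Monod-model log likelihood with the error scale marginalized
#'
#' The Monod equation `lambda(s) = lambda_max * s / (K_M + s)` relates the
#' specific growth rate to the nutrient concentration.  Assuming Gaussian
#' residuals with unknown scale sigma and the scale-invariant prior
#' `P(sigma) ~ 1/sigma`, marginalizing sigma gives
#' `log P(D | lambda_max, K_M) = -(N/2) * log(sum of squared residuals)`
#' up to an additive constant.
#'
#' @param lambda_max Maximal specific growth rate, per hour, `> 0`.
#' @param K_M Monod constant (concentration at half-maximal rate), `> 0`.
#' @param data Data frame (or list) with columns `s` (concentration) and
#'   `lambda` (measured rate).
#' @return Scalar log likelihood (up to a constant).
#' @export
monod_loglik <- function(lambda_max, K_M, data) {
  stopifnot(lambda_max > 0, K_M > 0)
  s <- data$s; lam <- data$lambda
  if (length(s) < 3L) stop("need at least 3 data points")
  rss <- sum((lam - lambda_max * s / (K_M + s))^2)
  if (rss <= 0) stop("perfect fit: marginalized likelihood is degenerate")
  -(length(s) / 2) * log(rss)
}

#' Fit the Monod equation by maximum likelihood
#'
#' Maximizes [monod_loglik()] with quasi-Newton (BFGS) from several starts,
#' optimizing on the log scale to enforce positivity.  Standard errors are
#' the square roots of the diagonal of the inverse of the negative
#' log-likelihood Hessian at the optimum, computed in the original
#' parameterization.
#'
#' @param data Data frame with columns `s` and `lambda`.
#' @return An object of class `"linseg_monod"`: `lambda_max`, `K_M`,
#'   `err_lambda_max`, `err_K_M`, `loglik`, `n_points`, `fitted`,
#'   `residuals`, `convergence`.
#' @export
fit_monod <- function(data) {
  s <- as.numeric(data$s); lam <- as.numeric(data$lambda)
  if (length(s) < 3L) stop("need at least 3 data points")
  if (length(unique(s)) < 2L) stop("need at least 2 distinct concentrations")
  if (any(s < 0)) stop("concentrations must be non-negative")
  df <- list(s = s, lambda = lam)
  N <- length(s)
  nll_log <- function(p) {
    lmx <- exp(p[1]); km <- exp(p[2])
    if (!is.finite(lmx) || !is.finite(km)) return(1e10)
    rss <- sum((lam - lmx * s / (km + s))^2)
    if (!is.finite(rss)) return(1e10)
    if (rss < 1e-300) return(-1e10)      # numerically perfect fit
    (N / 2) * log(rss)
  }
  spos <- s[s > 0]
  starts <- list(c(log(max(lam[lam > 0], 0.1)), log(min(spos))),
                 c(log(max(lam[lam > 0], 0.1)), log(stats::median(spos))))
  best <- NULL
  for (p0 in starts) {
    opt <- tryCatch(
      stats::optim(p0, nll_log, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  if (is.null(best)) stop("Monod fit failed to converge from all starts")
  lambda_max <- exp(best$par[1]); K_M <- exp(best$par[2])
  # finite-difference steps may probe non-positive parameters near the
  # optimum; penalize instead of erroring
  nll <- function(p) {
    if (any(p <= 0)) return(1e10)
    -monod_loglik(p[1], p[2], df)
  }
  H <- stats::optimHess(c(lambda_max, K_M), nll)
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) c(NA_real_, NA_real_))
  fitted <- lambda_max * s / (K_M + s)
  structure(list(lambda_max = lambda_max, K_M = K_M,
                 err_lambda_max = se[1], err_K_M = se[2],
                 loglik = -best$value, n_points = length(s),
                 fitted = fitted, residuals = lam - fitted,
                 convergence = best$convergence),
            class = "linseg_monod")
}

#' @export
print.linseg_monod <- function(x, ...) {
  cat(sprintf("<linseg_monod> lambda_max = %.4g +/- %.2g, K_M = %.4g +/- %.2g (n = %d)\n",
              x$lambda_max, x$err_lambda_max, x$K_M, x$err_K_M, x$n_points))
  invisible(x)
}
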