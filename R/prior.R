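#' Bounded uniform prior over segment coefficients
#'
#' Each coefficient m_k is a priori independent and uniform on
#' `[lo[k], hi[k]]`; the prior density inside the box is the reciprocal of
#' the box volume.  When the measurement error is unknown, `sigma_lo` and
#' `sigma_hi` bound its uniform prior.
#'
#' @param lo,hi Numeric K-vectors of coefficient bounds, `hi > lo`.
#' @param sigma_lo,sigma_hi Optional positive bounds for the unknown error.
#' @return An object of class `"linseg_prior"` with `log_volume_inv`
#'   precomputed.
#' @examples
#' coefficient_prior(c(0, -1), c(2, 1))$log_volume_inv  # -log(4)
#' @export
coefficient_prior <- function(lo, hi, sigma_lo = NULL, sigma_hi = NULL) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(length(lo) == length(hi))
  if (any(!is.finite(lo)) || any(!is.finite(hi)))
    stop("prior bounds must be finite")
  if (any(hi <= lo)) stop("each upper bound must exceed its lower bound")
  if (!is.null(sigma_lo) || !is.null(sigma_hi)) {
    stopifnot(!is.null(sigma_lo), !is.null(sigma_hi),
              sigma_lo > 0, sigma_hi > sigma_lo)
  }
  structure(
    list(lo = lo, hi = hi, K = length(lo),
         log_volume_inv = -sum(log(hi - lo)),
         sigma_lo = sigma_lo, sigma_hi = sigma_hi),
    class = "linseg_prior"
  )
}

#' @export
print.linseg_prior <- function(x, ...) {
  cat("<linseg_prior>\n")
  for (k in seq_len(x$K))
    cat(sprintf("  m%d in [%g, %g]\n", k, x$lo[k], x$hi[k]))
  if (!is.null(x$sigma_lo))
    cat(sprintf("  sigma in [%g, %g]\n", x$sigma_lo, x$sigma_hi))
  invisible(x)
}

#' Build the line-coefficient prior from one of three user inputs
#'
#' For the straight-line basis the user may give (a) both the intercept and
#' gradient ranges, (b) only the gradient range, or (c) only the maximal
#' range of y expected in the experiment.  Missing ranges are completed
#' from the data's x grid: a gradient range `[g_lo, g_hi]` implies an
#' intercept range `[min(-g_hi * x_max, g_lo * x_min),
#' max(-g_lo * x_max, g_hi * x_min)]`, and a y range `[y_lo, y_hi]` implies
#' a symmetric gradient range `[-g_max, g_max]` with
#' `g_max = (y_hi - y_lo) / min(diff(x))`.
#'
#' The completed intercept range is additionally widened, with a warning,
#' to contain the single-segment least-squares intercept if the rule above
#' would exclude it.
#'
#' @param ts A [time_series()] (supplies the x grid and, for the widening
#'   check, the y values).
#' @param intercept_range,gradient_range,y_range Numeric length-2 vectors;
#'   give `gradient_range` alone, `y_range` alone, or both
#'   `intercept_range` and `gradient_range`.
#' @return A [coefficient_prior()] for (intercept, gradient).
#' @examples
#' ts <- time_series(seq(0, 1, by = 0.1), sin(seq(0, 1, by = 0.1)))
#' build_coefficient_prior(ts, y_range = c(0, 2))
#' @export
build_coefficient_prior <- function(ts, intercept_range = NULL,
                                    gradient_range = NULL, y_range = NULL) {
  stopifnot(inherits(ts, "linseg_ts"))
  gi <- !is.null(intercept_range); gg <- !is.null(gradient_range)
  gy <- !is.null(y_range)
  ok <- (gi && gg && !gy) || (gg && !gi && !gy) || (gy && !gi && !gg)
  if (!ok)
    stop("give exactly one of: both intercept_range and gradient_range; ",
         "gradient_range alone; y_range alone")
  chk <- function(r, nm) {
    if (length(r) != 2L || any(!is.finite(r)) || r[2] <= r[1])
      stop(nm, " must be a finite, increasing length-2 vector")
    r
  }
  if (gy) {
    y_range <- chk(y_range, "y_range")
    dx <- min(diff(ts$x))
    if (dx <= 0) stop("duplicate x values: cannot derive a gradient range")
    gmax <- (y_range[2] - y_range[1]) / dx
    gradient_range <- c(-gmax, gmax)
  }
  gradient_range <- chk(gradient_range, "gradient_range")
  if (is.null(intercept_range)) {
    xmin <- ts$x[1]; xmax <- ts$x[ts$N]
    m2min <- gradient_range[1]; m2max <- gradient_range[2]
    intercept_range <- c(min(-m2max * xmax, m2min * xmin),
                         max(-m2min * xmax, m2max * xmin))
    # guard: the completed box must contain the global least-squares
    # intercept, else the evidence is computed under a prior excluding the
    # obvious fit
    fit <- stats::lm.fit(cbind(1, rep(ts$x, ts$N_r)), as.vector(ts$y))
    b0 <- fit$coefficients[1]
    if (is.finite(b0) && (b0 < intercept_range[1] || b0 > intercept_range[2])) {
      warning(sprintf(
        "derived intercept range [%g, %g] excludes the least-squares intercept %g; widening",
        intercept_range[1], intercept_range[2], b0))
      intercept_range <- range(c(intercept_range, b0))
    }
  } else {
    intercept_range <- chk(intercept_range, "intercept_range")
  }
  coefficient_prior(c(intercept_range[1], gradient_range[1]),
                    c(intercept_range[2], gradient_range[2]))
}
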