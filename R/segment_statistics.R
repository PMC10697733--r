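#' Best-fit summary of one segment
#'
#' For the straight-line basis reports the gradient and intercept of the
#' maximum-likelihood line plus the coefficient of determination R2; for
#' other bases reports the coefficient vector and R2 only.  R2 pools
#' replicates: the total sum of squares is about the grand mean of all the
#' segment's replicate values, matching the likelihood's treatment of
#' replicates as exchangeable draws.
#'
#' @param kernel A [segment_kernel()] (or a table entry via [get_kernel()]).
#' @param ts The [time_series()] the kernel was built from.
#' @return An object of class `"linseg_segstats"`: `start`, `end`,
#'   `npoints`, `coefficients`, `r_squared`, `degenerate`, and for lines
#'   `gradient` and `intercept`.
#' @export
segment_stats <- function(kernel, ts) {
  stopifnot(inherits(kernel, "linseg_kernel"), inherits(ts, "linseg_ts"))
  i0 <- kernel$i0; i1 <- kernel$i1
  x <- ts$x[i0:i1]
  y <- ts$y[i0:i1, , drop = FALSE]
  basis <- kernel$basis
  fit <- as.vector(t(basis_matrix(basis, x)) %*% kernel$m_bar)
  rss <- sum((y - fit)^2)                      # recycles fit across replicates
  tss <- sum((y - mean(y))^2)
  degenerate <- tss <= .Machine$double.eps * max(1, sum(y^2))
  r2 <- if (degenerate) {
    if (rss <= .Machine$double.eps * max(1, sum(y^2))) 1 else 0
  } else {
    max(0, min(1, 1 - rss / tss))
  }
  is_line <- basis$K == 2L && identical(basis$names, c("1", "x"))
  out <- list(start = i0, end = i1, npoints = kernel$ell,
              coefficients = kernel$m_bar, r_squared = r2,
              degenerate = degenerate)
  if (is_line) {
    out$intercept <- kernel$m_bar[1L]
    out$gradient <- kernel$m_bar[2L]
  }
  structure(out, class = "linseg_segstats")
}

#' @export
print.linseg_segstats <- function(x, ...) {
  if (!is.null(x$gradient))
    cat(sprintf("<segment [%d, %d]> gradient %.4g, intercept %.4g, R2 %.4f%s\n",
                x$start, x$end, x$gradient, x$intercept, x$r_squared,
                if (x$degenerate) " (degenerate)" else ""))
  else
    cat(sprintf("<segment [%d, %d]> K = %d coefficients, R2 %.4f%s\n",
                x$start, x$end, length(x$coefficients), x$r_squared,
                if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Select one segment from a list of per-segment statistics
#'
#' @param stats A list of [segment_stats()] results (e.g. the `stats` field
#'   of a [partition()]).
#' @param criterion `"gradient"` for the largest gradient (e.g. the log
#'   phase of a growth curve), `"r2"` for the largest R2, or `"index"` for
#'   an explicit position.
#' @param index Position used when `criterion = "index"`.
#' @return The selected element, with attribute `"which"` giving its
#'   position; ties go to the earliest segment.
#' @export
select_segment <- function(stats, criterion = c("gradient", "r2", "index"),
                           index = 1L) {
  criterion <- match.arg(criterion)
  if (!length(stats)) stop("empty segment list")
  w <- switch(criterion,
    gradient = {
      g <- vapply(stats, function(s) {
        if (is.null(s$gradient)) stop("gradient criterion needs a line basis")
        s$gradient
      }, numeric(1))
      which.max(g)                       # which.max takes the first maximum
    },
    r2 = which.max(vapply(stats, function(s) s$r_squared, numeric(1))),
    index = {
      if (index < 1L || index > length(stats)) stop("index out of range")
      as.integer(index)
    })
  out <- stats[[w]]
  attr(out, "which") <- w
  out
}
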