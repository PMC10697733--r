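#' Construct a validated 1D series with replicates
#'
#' Bundles an ascending `x` grid (time in hours, or dilution factor), one or
#' more replicate observation vectors, and an optional per-point measurement
#' error shared across replicates.
#'
#' @param x Numeric vector, strictly ascending, no missing values.
#' @param y Numeric vector, matrix, or data frame of observations.  A matrix
#'   or data frame holds one replicate per column; each column must have
#'   `length(x)` rows.
#' @param sigma Optional numeric vector of per-point measurement errors
#'   (standard deviations), strictly positive, length `length(x)`.
#'
#' @return An object of class `"linseg_ts"` with fields `x` (length `N`),
#'   `y` (an `N` x `N_r` matrix), `sigma` (or `NULL`), `N`, and `N_r`.
#' @examples
#' ts <- time_series(0:9, cbind(rnorm(10), rnorm(10)))
#' ts$N_r
#' @export
time_series <- function(x, y, sigma = NULL) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("x contains missing values")
  if (length(x) < 2L) stop("need at least two points")
  if (any(diff(x) <= 0)) {
    bad <- which(diff(x) <= 0)
    stop("x must be strictly ascending; violation after row(s) ",
         paste(bad, collapse = ", "))
  }
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  if (nrow(y) != length(x))
    stop("y must have one row per x value (", length(x), " expected, got ",
         nrow(y), ")")
  if (anyNA(y)) stop("y contains missing values")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(x))
      stop("sigma must have length ", length(x))
    if (anyNA(sigma) || any(sigma <= 0))
      stop("sigma must be strictly positive with no missing values")
  }
  structure(
    list(x = x, y = y, sigma = sigma, N = length(x), N_r = ncol(y)),
    class = "linseg_ts"
  )
}

#' @export
print.linseg_ts <- function(x, ...) {
  cat(sprintf("<linseg_ts> N = %d points, N_r = %d replicate(s), %s\n",
              x$N, x$N_r,
              if (is.null(x$sigma)) "no per-point error"
              else "per-point error attached"))
  cat(sprintf("  x range: [%g, %g]\n", x$x[1], x$x[x$N]))
  invisible(x)
}

#' Read a series from a delimited text table
#'
#' Expects a header row; the first column is `x`, a column named `sigma`
#' (if present) is bound as the per-point error, and all remaining columns
#' are replicates.  The delimiter is a comma for `.csv` files and a tab
#' otherwise.
#'
#' @param path Path to a CSV or TSV file.
#' @param sigma_column Name of the error column; set `NULL` to ignore any
#'   `sigma` column.
#' @return A [time_series()] object.
#' @export
read_timeseries <- function(path, sigma_column = "sigma") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("table needs an x column and at least one y column")
  x <- df[[1L]]
  if (anyNA(x)) stop("x column contains missing values")
  dup <- which(duplicated(x))
  if (length(dup))
    stop("duplicate x values at row(s) ", paste(dup, collapse = ", "))
  sigma <- NULL
  ycols <- names(df)[-1L]
  if (!is.null(sigma_column) && sigma_column %in% ycols) {
    sigma <- df[[sigma_column]]
    ycols <- setdiff(ycols, sigma_column)
  }
  if (!length(ycols)) stop("no y columns found")
  time_series(x, as.matrix(df[ycols]), sigma = sigma)
}

#' Write a series to a delimited text table
#'
#' Inverse of [read_timeseries()]: first column `x`, replicate columns
#' `y1..yR`, and a `sigma` column when the series carries one.
#'
#' @param ts A [time_series()] object.
#' @param path Output path (`.csv` for comma-separated, tab otherwise).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "linseg_ts"))
  df <- data.frame(x = ts$x)
  yn <- colnames(ts$y)
  if (is.null(yn)) yn <- paste0("y", seq_len(ts$N_r))
  for (r in seq_len(ts$N_r)) df[[yn[r]]] <- ts$y[, r]
  if (!is.null(ts$sigma)) df$sigma <- ts$sigma
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
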