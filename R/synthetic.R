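# Synthetic benchmark: continuous piecewise-linear truths with gradients
# sampled uniformly in ANGLE (not slope), Gaussian noise, and replicates.

#' Sample a continuous piecewise-linear truth
#'
#' Generates `M` contiguous linear segments, each with between 10 and 50
#' points at unit spacing by default.  The angle theta of each segment to
#' the x-axis is drawn uniformly on `[-atan(20), atan(20)]` (so gradients
#' `tan(theta)` lie in `[-20, 20]`), redrawing until each neighbouring pair
#' of segments differs in angle by more than `theta0`.  The truth is exact
#' at segment joins (continuous), with the first segment's intercept at 0.
#'
#' @param M Number of segments, 1 to 10 in the benchmark.
#' @param theta0 Minimum adjacent-angle difference, in degrees.
#' @param points_per_segment Length-2 integer range of points per segment.
#' @param dx Grid spacing.
#' @param theta_range Angle bounds in radians.
#' @param seed Optional integer seed.
#' @return An object of class `"linseg_synthfun"`: `x`, `f` (noiseless
#'   values), `boundaries` (indices of each segment's last point, length
#'   `M - 1`), `gradients`, `theta`, `seg_lengths`, `M`.
#' @export
sample_piecewise_function <- function(M, theta0 = 10,
                                      points_per_segment = c(10L, 50L),
                                      dx = 1, theta_range = c(-atan(20), atan(20)),
                                      seed = NULL) {
  stopifnot(M >= 1, theta0 >= 0, length(points_per_segment) == 2L)
  if (!is.null(seed)) set.seed(seed)
  theta0_rad <- theta0 * pi / 180
  if (theta0_rad >= diff(range(theta_range)))
    stop("theta0 exceeds the full angle range; constraint unsatisfiable")
  len_rng <- points_per_segment[1]:points_per_segment[2]
  lens <- if (length(len_rng) == 1L) rep(len_rng, M)
    else sample(len_rng, M, replace = TRUE)
  theta <- numeric(M)
  theta[1] <- stats::runif(1, theta_range[1], theta_range[2])
  if (M >= 2) {
    for (s in 2:M) {
      ok <- FALSE
      for (try in seq_len(10000L)) {
        cand <- stats::runif(1, theta_range[1], theta_range[2])
        if (abs(cand - theta[s - 1]) > theta0_rad) { ok <- TRUE; break }
      }
      if (!ok) stop("could not satisfy the adjacent-angle constraint for ",
                    "theta0 = ", theta0, " degrees")
      theta[s] <- cand
    }
  }
  g <- tan(theta)
  N <- sum(lens)
  x <- (seq_len(N) - 1) * dx
  bnd <- cumsum(lens)[-M]                # last point of segments 1..M-1
  f <- numeric(N)
  start <- 1L
  x_anchor <- x[1]; y_anchor <- 0
  for (s in seq_len(M)) {
    end <- cumsum(lens)[s]
    f[start:end] <- y_anchor + g[s] * (x[start:end] - x_anchor)
    x_anchor <- x[end]; y_anchor <- f[end]   # kink at the segment's last point
    start <- end + 1L
  }
  structure(list(x = x, f = f, boundaries = bnd, gradients = g,
                 theta = theta, seg_lengths = lens, M = as.integer(M)),
            class = "linseg_synthfun")
}

#' Add Gaussian noise replicates to a synthetic truth
#'
#' @param synth A [sample_piecewise_function()] result.
#' @param sigma Noise standard deviation, `>= 0`.
#' @param n_replicates Number of independent noisy copies (benchmark
#'   default: 3).
#' @param seed Optional integer seed.
#' @return An object of class `"linseg_synthdata"`: `ts` (a
#'   [time_series()]), `truth_boundaries`, `truth_gradients`,
#'   `truth_values`, `M`, `sigma`, `n_replicates`.
#' @export
add_noise_replicates <- function(synth, sigma, n_replicates = 3L,
                                 seed = NULL) {
  stopifnot(inherits(synth, "linseg_synthfun"), sigma >= 0, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- length(synth$x)
  y <- synth$f + matrix(stats::rnorm(N * n_replicates, 0, sigma),
                        N, n_replicates)
  structure(list(ts = time_series(synth$x, y),
                 truth_boundaries = synth$boundaries,
                 truth_gradients = synth$gradients,
                 truth_values = synth$f,
                 M = synth$M, sigma = sigma,
                 n_replicates = as.integer(n_replicates)),
            class = "linseg_synthdata")
}

#' Generate the synthetic benchmark suite
#'
#' The full benchmark combines `n_functions` piecewise-linear truths (with
#' the segment count drawn uniformly from `M_range`) per minimum-angle
#' value, three minimum-angle values, and six noise levels: 200 x 3 x 6 =
#' 3600 datasets at full scale.  One root seed spawns per-dataset child
#' seeds so any single dataset is reproducible in isolation.
#'
#' @param seed Root integer seed.
#' @param n_functions Truths per `theta0` value (200 at full scale; reduce
#'   for desk-scale runs).
#' @param theta0_values Minimum adjacent-angle gaps, degrees.
#' @param sigma_values Noise standard deviations.
#' @param M_range Candidate segment counts for the truths.
#' @param n_replicates Replicates per dataset.
#' @return A list: `datasets` (list of `"linseg_synthdata"`, each tagged
#'   with `id`, `fun_id`, `theta0`) and `manifest` (a data frame with one
#'   row per dataset: id, fun_id, M, theta0, sigma, seeds).
#' @export
generate_benchmark_suite <- function(seed, n_functions = 200L,
                                     theta0_values = c(5, 10, 20),
                                     sigma_values = c(0.25, 0.5, 1, 2, 4, 8),
                                     M_range = 1:10, n_replicates = 3L) {
  set.seed(seed)
  n_fun_total <- n_functions * length(theta0_values)
  n_total <- n_fun_total * length(sigma_values)
  Ms <- sample(M_range, n_fun_total, replace = TRUE)
  fun_seeds <- sample.int(.Machine$integer.max - 1L, n_fun_total)
  noise_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  datasets <- vector("list", n_total)
  manifest <- data.frame(id = seq_len(n_total), fun_id = 0L, M = 0L,
                         theta0 = 0, sigma = 0, fun_seed = 0L,
                         noise_seed = 0L)
  id <- 0L; fi <- 0L
  for (theta0 in theta0_values) {
    for (fn in seq_len(n_functions)) {
      fi <- fi + 1L
      synth <- sample_piecewise_function(Ms[fi], theta0 = theta0,
                                         seed = fun_seeds[fi])
      for (sg in sigma_values) {
        id <- id + 1L
        d <- add_noise_replicates(synth, sg, n_replicates,
                                  seed = noise_seeds[id])
        d$id <- id; d$fun_id <- fi; d$theta0 <- theta0
        datasets[[id]] <- d
        manifest[id, ] <- list(id, fi, synth$M, theta0, sg,
                               fun_seeds[fi], noise_seeds[id])
      }
    }
  }
  list(datasets = datasets, manifest = manifest)
}

#' Write a benchmark suite to a directory of CSV files
#'
#' Writes `manifest.csv` plus one `dataset_<id>.csv` per dataset in the
#' standard table layout (x, replicate columns).
#'
#' @param suite A [generate_benchmark_suite()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_benchmark_suite <- function(suite, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(suite$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  for (d in suite$datasets)
    write_timeseries(d$ts, file.path(dir, sprintf("dataset_%d.csv", d$id)))
  invisible(dir)
}
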