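test_that("partition counting matches enumeration and the closed form", {
  expect_equal(count_valid_partitions(9, 3, 3), 1)
  expect_equal(count_valid_partitions(10, 2, 3), 5)
  expect_equal(count_valid_partitions(5, 1, 3), 1)
  expect_equal(count_valid_partitions(5, 2, 3), 0)
  for (N in c(6, 9, 12, 17, 23, 30)) {
    for (M in 1:5) {
      if (N < M * 3) next
      cnt <- count_valid_partitions(N, M, 3)
      expect_equal(cnt, nrow(enum_boundaries(N, M, 3)))
      expect_equal(cnt, choose(N - M * 3 + M - 1, M - 1))
    }
  }
  # a different lmin
  expect_equal(count_valid_partitions(14, 3, 4),
               nrow(enum_boundaries(14, 3, 4)))
})

test_that("boundary log prior is minus the log count", {
  expect_equal(log_prior_boundaries(10, 2, 3), -log(5))
  expect_equal(log_prior_boundaries(9, 3, 3), 0)
  expect_equal(log_prior_boundaries(5, 2, 3), -Inf)
  set.seed(31)
  for (rep in 1:10) {
    N <- sample(8:25, 1); M <- sample(1:4, 1)
    if (N < 3 * M) next
    expect_equal(exp(log_prior_boundaries(N, M, 3)) *
                   count_valid_partitions(N, M, 3), 1)
  }
})

test_that("variable elimination equals exhaustive enumeration", {
  set.seed(32)
  prior <- wide_prior()
  lin <- make_linear_basis()
  for (rep in 1:8) {
    N <- sample(9:15, 1)
    ts <- random_ts(N, N_r = sample(1:2, 1))
    tab <- precompute_segment_table(lin, ts, prior, "known", sigma = 1)
    for (M in 1:3) {
      ev <- log_evidence_known_sigma(tab, M)
      brute <- log_prior_boundaries(N, M, 3) + brute_log_sum(tab$L, N, M, 3)
      expect_equal(ev, brute, tolerance = 1e-10)
    }
  }
  # M = 1 is the single-segment marginal with zero log prior
  ts <- random_ts(10, seed = 33)
  tab <- precompute_segment_table(lin, ts, prior, "known", sigma = 1)
  expect_equal(log_evidence_known_sigma(tab, 1), tab$L[1, 10])
})

test_that("select_M is an argmax with parsimony tie-breaking", {
  expect_equal(select_M(c(-10, -5, -7)), 2L)
  expect_equal(select_M(c(-10, -5, -5)), 2L)
  expect_equal(select_M(c(-3)), 1L)
  expect_equal(select_M(c(-Inf, -4, -Inf), M_values = 1:3), 2L)
  expect_error(select_M(c(-Inf, -Inf)), "feasible")
})

test_that("posterior boundary moments match enumeration and normalize", {
  set.seed(34)
  prior <- wide_prior()
  lin <- make_linear_basis()
  for (rep in 1:5) {
    N <- sample(10:14, 1)
    ts <- random_ts(N)
    tab <- precompute_segment_table(lin, ts, prior, "known", sigma = 1)
    for (M in 2:3) {
      mom <- posterior_boundary_moments(tab, M)
      br <- brute_moments(tab$L, N, M, 3)
      expect_equal(mom$mean, br$mean, tolerance = 1e-8)
      expect_equal(mom$var, br$var, tolerance = 1e-8)
      expect_equal(br$total, 1, tolerance = 1e-10)  # posterior normalizes
    }
  }
})

test_that("a sharp corner and symmetric data pin the boundary", {
  ts <- vshape_ts(N = 30, corner = 15, noise = 0.05)
  tab <- precompute_segment_table(make_linear_basis(), ts, wide_prior(),
                                  "known", sigma = 0.05)
  mom <- posterior_boundary_moments(tab, 2)
  expect_lt(abs(mom$mean[1] - 15), 1)
  expect_lt(mom$var[1], 1)
  # mirror-symmetric V with the corner point shared by both lines: the two
  # zero-residual boundary placements (corner in the left or right segment)
  # are equally likely, so the mean sits halfway between them
  x <- 1:19
  y <- abs(x - 10)
  tss <- time_series(x, y)
  tabs <- precompute_segment_table(make_linear_basis(), tss, wide_prior(),
                                   "known", sigma = 0.05)
  moms <- posterior_boundary_moments(tabs, 2)
  expect_equal(moms$mean[1], 9.5, tolerance = 1e-6)
})

test_that("partition selects one segment for a single noisy line", {
  set.seed(35)
  x <- 0:29
  ts <- time_series(x, 1.3 + 0.7 * x + rnorm(30, 0, 0.5))
  fit <- partition(ts, wide_prior(), sigma = 0.5, M_max = 4, quiet = TRUE)
  expect_equal(fit$M_best, 1L)
  expect_equal(nrow(fit$segments), 1L)
  expect_equal(fit$segments[1, ], c(start = 1L, end = 30L))
})

test_that("partition recovers a 3-segment truth and tiles the series", {
  synth <- sample_piecewise_function(3, theta0 = 10, seed = 36)
  d <- add_noise_replicates(synth, 0.25, 3, seed = 37)
  prior <- build_coefficient_prior(d$ts, gradient_range = c(-25, 25))
  fit <- partition(d$ts, prior, sigma = 0.25, M_max = 6, quiet = TRUE)
  expect_equal(fit$M_best, 3L)
  expect_true(all(abs(fit$boundaries_index - d$truth_boundaries) <= 2))
  # segments tile 1..N with no gaps or overlaps
  expect_equal(unname(fit$segments[1, "start"]), 1L)
  expect_equal(unname(fit$segments[fit$M_best, "end"]), d$ts$N)
  if (fit$M_best > 1)
    expect_equal(fit$segments[-1, "start"], fit$segments[-fit$M_best, "end"] + 1L,
                 ignore_attr = TRUE)
  expect_true(all(diff(fit$boundaries_mean) >= 3))
})

test_that("boundary posteriors are affine-equivariant in y", {
  set.seed(38)
  ts <- vshape_ts(N = 24, corner = 9, noise = 0.3, seed = 39)
  prior1 <- coefficient_prior(c(-30, -10), c(30, 10))
  tab1 <- precompute_segment_table(make_linear_basis(), ts, prior1,
                                   "known", sigma = 0.3)
  ts2 <- time_series(ts$x, ts$y + 7)
  prior2 <- coefficient_prior(c(-30 + 7, -10), c(30 + 7, 10))
  tab2 <- precompute_segment_table(make_linear_basis(), ts2, prior2,
                                   "known", sigma = 0.3)
  m1 <- posterior_boundary_moments(tab1, 2)
  m2 <- posterior_boundary_moments(tab2, 2)
  expect_equal(m1$mean, m2$mean, tolerance = 1e-9)
  expect_equal(m1$var, m2$var, tolerance = 1e-8)
  expect_equal(log_evidence_known_sigma(tab1, 2),
               log_evidence_known_sigma(tab2, 2), tolerance = 1e-9)
})

test_that("infeasible or short series are handled", {
  ts <- random_ts(5, seed = 40)
  expect_equal(log_evidence_known_sigma(
    precompute_segment_table(make_linear_basis(), ts, wide_prior(),
                             "known", sigma = 1), 2), -Inf)
  expect_warning(
    fit <- partition(ts, wide_prior(), sigma = 1, M_max = 3, quiet = TRUE),
    "M = 1")
  expect_equal(fit$M_best, 1L)
})
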