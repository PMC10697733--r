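# linseg

Bayesian partitioning of a 1D series into contiguous segments, each
described by a linear combination of basis functions — straight lines by
default.  `linseg` answers, with calibrated uncertainty, the questions
scientists usually settle by eye: *how many* linear regimes does this
series contain, and *where* are their boundaries?

It was built for microbial growth analysis — finding the range of optical
density (OD) that is proportional to cell number, detecting the
exponential (log) phase of growth curves, and fitting Monod kinetics — but
the engine is generic for any ordered series with optional replicates.

## The statistics in brief

For observations $(x_j, y_j^{(r)})$, $j = 1\dots N$, $r = 1\dots N_r$, and
a candidate segment count $M$, the evidence is

$$P(D \mid M) = f(N, M, \ell_{\min}) \sum_{\mathbf n}
  \prod_{i=1}^{M} P(D_i \mid n_i{+}1,\, n_{i+1}),$$

a sum over all boundary vectors $\mathbf n$ (each segment at least
$\ell_{\min}$ points) of closed-form Gaussian marginal likelihoods: each
segment's coefficients are integrated out under a bounded uniform prior.
The sum is computed exactly by variable elimination in $O(MN^2)$, in log
space.  The $M$ with the greatest evidence wins; boundary posteriors give
means and variances for each change point.  Measurement error can be known
per point, a known scalar, or unknown — in which case a shared
$\sigma$ is estimated by expectation–maximization and marginalized
numerically.  See `vignettes/segmentation-methods.Rmd` for the full
account.

## Worked example

Three noisy linear segments, three replicates, known noise:

```r
library(linseg)
synth <- sample_piecewise_function(3, theta0 = 10, seed = 11)
d     <- add_noise_replicates(synth, sigma = 0.25, n_replicates = 3, seed = 12)
d$truth_boundaries            # 43 77
round(d$truth_gradients, 3)   # 5.277 -3.089 -0.743

prior <- build_coefficient_prior(d$ts, gradient_range = c(-25, 25))
fit   <- partition(d$ts, prior, sigma = 0.25, quiet = TRUE)
print(fit)
```

```
<linseg_partition> M_best = 3 (of 10 evaluated), known error
  log evidence: M=1: -6658359.31, M=2: -129998.81, M=3: -64.24, M=4: -78.16, ...
  boundaries (posterior mean +/- sd): 42.42 +/- 0.49, 76.52 +/- 0.50
  segment 1 [1, 42]: gradient 5.278, intercept -0.02928, R2 1.0000
  segment 2 [43, 77]: gradient -3.087, intercept 351.2, R2 0.9999
  segment 3 [78, 102]: gradient -0.7412, intercept 172.9, R2 0.9976
```

Reading this: three segments are decisively favoured (log-evidence gap of
14 to the nearest rival, i.e. a Bayes factor of about $e^{14}$); the two
change points are located at indices 42.4 and 76.5 with sub-index
uncertainty (truth: 43 and 77 — the boundary is the last index of the
segment to its left); recovered gradients match the generating slopes to
three figures.

Growth applications follow the same pattern:

```r
res <- od_linear_range(cal_ts, build_coefficient_prior(cal_ts, y_range = c(0, 2)))
res$scale_factor            # OD per dilution-factor unit over the linear range

lp <- find_log_phase(growth_ts,
        function(l) build_coefficient_prior(l, gradient_range = c(0, 5)))
lp$specific_growth_rate     # h^-1, gradient of log OD in the selected segment

fit_monod(data.frame(s = conc, lambda = rates))   # lambda_max, K_M +/- SEs
```

There is also a CLI: `run_cli(c("segment", "--input", "data.csv",
"--sigma", "unknown", "--prior-y", "0", "2", "--out", "report.json"))`,
with subcommands `segment | od-linear-range | log-phase | monod |
simulate`.

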