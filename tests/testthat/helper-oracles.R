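# Independent oracles and fixture builders used across the test files.

# pinball (check) loss of the line y = a + b x, written independently of the
# package's solver
oracle_pinball <- function(y, x, tau, a, b) {
  u <- y - a - b * x
  sum(u * (tau - (u < 0)))
}

# brute-force minimum of the pinball loss over all lines through pairs of
# data points (an optimal quantile-regression line interpolates two points)
oracle_enum_loss <- function(y, x, tau) {
  n <- length(y)
  best <- Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]
      if (abs(dx) < 1e-12) next
      b <- (y[i] - y[j]) / dx
      a <- y[i] - b * x[i]
      l <- oracle_pinball(y, x, tau, a, b)
      if (l < best) best <- l
    }
  }
  best
}

# small simulated analysis set: adjusted trait + adjusted score under the
# location-scale truth
make_adjusted_draw <- function(n = 1000, n_snps = 30, theta = 0.3,
                               sigma = 20, seed = 1) {
  cfg <- simulation_config(n_subjects = n,
                           snps = default_snp_specs(n_snps),
                           theta = theta, sigma = sigma, seed = seed)
  ch <- simulate_cohort(cfg)
  wt <- weights_table(cfg$snps$id, "G", "A", cfg$snps$beta)
  grs <- compute_grs(ch$dosages, wt)
  list(cohort = ch, config = cfg,
       y = adjust_covariates(ch$phenotype, ch$subjects),
       x = adjust_covariates(as.numeric(grs), ch$subjects))
}

# toy profile with chosen slopes/SEs (for arithmetic-level operations that
# are pure functions of the profile)
toy_profile <- function(percentiles, slopes, ses = rep(0.1, length(slopes)),
                        cov = NULL, ols_slope = mean(slopes),
                        ols_se = 0.1, ols_r2 = 0.05) {
  if (is.null(cov)) cov <- diag(ses^2)
  quantpen:::new_slope_profile(taus = percentiles / 100, slope = slopes,
                               se = ses, cov = cov, ols_slope = ols_slope,
                               ols_se = ols_se, ols_r2 = ols_r2,
                               n = NA_integer_, B = NA_integer_, seed = NA)
}
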