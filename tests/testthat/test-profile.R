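test_that("zero-noise data give a degenerate profile", {
  set.seed(110)
  x <- rnorm(120)
  y <- 2 * x
  p <- suppressMessages(fit_profile(y, x, grid = quantile_grid(step = 10),
                                    B = 60, seed = 1))
  expect_true(all(abs(p$slope - 2) < 1e-9))
  expect_true(all(p$se < 1e-8))
  expect_equal(p$ols_slope, 2, tolerance = 1e-12)
  expect_equal(p$ols_r2, 1, tolerance = 1e-12)
})

test_that("homoscedastic profiles stay near the least-squares slope", {
  # under theta = 0 the profile is flat; count grid points straying beyond
  # 4 bootstrap SEs from the OLS slope over independent replicates
  ok <- logical(10)
  for (r in 1:10) {
    draw <- make_adjusted_draw(n = 1000, n_snps = 10, theta = 0,
                               seed = 200 + r)
    p <- suppressMessages(fit_profile(draw$y, draw$x,
                                      grid = quantile_grid(step = 5),
                                      B = 100, seed = r))
    ok[r] <- all(abs(p$slope - p$ols_slope) <= 4 * p$se)
  }
  expect_gte(mean(ok), 0.9)
})

test_that("profile structure satisfies its invariants and is deterministic", {
  draw <- make_adjusted_draw(n = 400, n_snps = 5, theta = 0.3, seed = 111)
  p <- suppressMessages(fit_profile(draw$y, draw$x,
                                    grid = quantile_grid(step = 10),
                                    B = 80, seed = 5))
  expect_equal(p$se, sqrt(diag(p$cov)), tolerance = 1e-12)
  expect_equal(p$cov, t(p$cov), tolerance = 1e-12)
  expect_gte(min(eigen(p$cov, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_length(p$slope, length(quantile_grid(step = 10)))
  p2 <- suppressMessages(fit_profile(draw$y, draw$x,
                                     grid = quantile_grid(step = 10),
                                     B = 80, seed = 5))
  expect_identical(p$slope, p2$slope)
  expect_identical(p$cov, p2$cov)
  expect_error(fit_profile(draw$y, draw$x, B = 10), "at least 50")
})

test_that("bootstrap covariance is stable across independent runs", {
  draw <- make_adjusted_draw(n = 600, n_snps = 8, theta = 0.3, seed = 112)
  grid <- quantile_grid(step = 10)
  p_full <- suppressMessages(fit_profile(draw$y, draw$x, grid = grid,
                                         B = 600, seed = 1))
  p_h1 <- suppressMessages(fit_profile(draw$y, draw$x, grid = grid,
                                       B = 300, seed = 2))
  p_h2 <- suppressMessages(fit_profile(draw$y, draw$x, grid = grid,
                                       B = 300, seed = 3))
  cov_halves <- (p_h1$cov + p_h2$cov) / 2
  rel <- norm(cov_halves - p_full$cov, "F") / norm(p_full$cov, "F")
  # Monte-Carlo tolerance: covariance entries fluctuate at O(sqrt(2/B))
  expect_lt(rel, 4 / sqrt(300))
})

test_that("the linear-contrast trend reproduces direct contrast arithmetic", {
  # exactly linear profile: delta is the line's slope regardless of Sigma
  k <- c(10, 30, 50, 70, 90)
  lin <- toy_profile(k, 0.1 + 0.01 * k, ses = rep(0.05, 5))
  expect_equal(trend_test(lin)$delta, 0.01, tolerance = 1e-12)
  flat <- toy_profile(k, rep(0.4, 5))
  expect_equal(trend_test(flat)$delta, 0, tolerance = 1e-12)

  # hand-worked 5-point example: c = (-40,-20,0,20,40), sum c^2 = 4000,
  # sum c*beta = 34 -> delta = 0.0085; c'Sigma c = 88 -> SE = sqrt(88)/4000
  pr <- toy_profile(k, c(0.2, 0.3, 0.5, 0.6, 0.9),
                    cov = diag(c(0.01, 0.01, 0.01, 0.01, 0.04)))
  tr <- trend_test(pr)
  expect_equal(tr$delta, 0.0085, tolerance = 1e-12)
  expect_equal(tr$se, sqrt(88) / 4000, tolerance = 1e-12)
  expect_equal(tr$p, 2 * pnorm(-tr$delta / tr$se), tolerance = 1e-12)

  # non-PSD covariance is projected with a warning
  bad <- toy_profile(k, c(0.2, 0.3, 0.5, 0.6, 0.9),
                     cov = matrix(-0.01, 5, 5) + diag(0.005, 5))
  expect_warning(trend_test(bad), "PSD")
  expect_error(trend_test(toy_profile(c(10, 90), c(0.1, 0.2))), "3 grid")
})

test_that("precision weighting is a valid alternative contrast", {
  k <- c(10, 30, 50, 70, 90)
  pr <- toy_profile(k, 0.1 + 0.01 * k,
                    cov = diag(c(0.01, 0.01, 0.01, 0.01, 0.04)))
  # an exactly linear profile yields the same slope under any weighting
  expect_equal(trend_test(pr, weighting = "precision")$delta, 0.01,
               tolerance = 1e-12)
})

test_that("slopes interpolate and clamp across percentiles", {
  pr <- toy_profile(c(10, 11, 50, 90), c(0.28, 0.30, 0.5, 0.9))
  expect_equal(slope_at(pr, 10), 0.28)
  expect_equal(slope_at(pr, 10.5), 0.29)
  expect_equal(slope_at(pr, 2), 0.28)   # clamped below the grid
  expect_equal(slope_at(pr, 100), 0.9)  # clamped above
  expect_error(slope_at(pr, -1))
})

test_that("fold ratios and differences match the published arithmetic", {
  ldl <- toy_profile(c(10, 90), c(0.281, 1.384), ols_slope = 0.801)
  fr <- fold_ratio(ldl)
  expect_equal(round(fr$ratio, 2), 4.93)
  expect_equal(round(fr$difference, 2), 1.10)
  tc <- toy_profile(c(10, 90), c(0.43, 1.32), ols_slope = 1.01)
  expect_equal(round(fold_ratio(tc)$ratio, 2), 3.07)
  flat <- toy_profile(c(10, 90), c(0.5, 0.5))
  expect_equal(fold_ratio(flat)$ratio, 1)
  expect_equal(fold_ratio(flat)$difference, 0)
  zero <- toy_profile(c(10, 90), c(0, 0.5))
  expect_warning(fr0 <- fold_ratio(zero), "undefined")
  expect_true(is.na(fr0$ratio))
  expect_equal(fr0$difference, 0.5)
})

test_that("the OLS confidence band covers the expected percentile range", {
  k <- c(10, 30, 50, 70, 90)
  flat <- toy_profile(seq(5, 95, 5), rep(0.5, 19), ols_slope = 0.5,
                      ols_se = 0.05)
  band <- ci_coverage_band(flat)
  expect_equal(c(band$low, band$high), c(5, 95))
  expect_equal(band$fraction_outside, 0)

  # hand-checked toy: band 0.5 +/- 1.96*0.1 = (0.304, 0.696) contains the
  # middle three slopes only
  pr <- toy_profile(k, c(0.2, 0.4, 0.5, 0.6, 0.8), ols_slope = 0.5,
                    ols_se = 0.1)
  band2 <- ci_coverage_band(pr)
  expect_equal(c(band2$low, band2$high), c(30, 70))
  expect_equal(band2$fraction_outside, 0.4)

  # strictly increasing profile: a single contiguous band
  inc <- toy_profile(seq(5, 95, 5), seq(0.1, 1.9, 0.1), ols_slope = 1,
                     ols_se = 0.15)
  band3 <- ci_coverage_band(inc)
  inside <- abs(inc$slope - 1) <= 1.96 * 0.15
  expect_equal(band3$fraction_outside, mean(!inside))
  expect_equal(band3$low, min(inc$percentile[inside]))
  expect_equal(band3$high, max(inc$percentile[inside]))
})
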