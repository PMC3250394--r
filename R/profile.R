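#' Percentile grid for quantile profiling
#'
#' The default grid covers the 5th through 95th percentile in 1-percent
#' steps (91 points); a coarser step trades resolution for speed in
#' simulation loops.
#'
#' @param step grid step in percent (must divide 90 evenly enough to keep
#'   5 and 95 on the grid).
#' @return numeric vector of quantile levels in (0, 1).
#' @export
quantile_grid <- function(step = 1) {
  stopifnot(step > 0, step <= 45)
  taus <- seq(5, 95, by = step) / 100
  if (abs(taus[length(taus)] - 0.95) > 1e-9)
    stop("step must place 95 on the grid")
  taus
}

#' Quantile regression of a trait on a score at one quantile
#'
#' Minimizes the pinball loss
#' \eqn{\sum_i \rho_\tau(y_i - a - b x_i)}, with
#' \eqn{\rho_\tau(u) = u(\tau - 1[u<0])}, for the two-parameter line. For
#' small samples the exact minimizer is found by enumerating all lines
#' through data-point pairs (an optimal solution always interpolates two
#' points); larger samples use iteratively reweighted least squares on a
#' smoothed objective followed by an exact refit through the lowest-residual
#' point pairs.
#'
#' @param y response (adjusted trait).
#' @param x predictor (adjusted score); must vary.
#' @param tau quantile level in (0, 1).
#' @return named numeric: `intercept`, `slope`, `loss` (attained pinball
#'   loss).
#' @export
quantile_fit <- function(y, x, tau) {
  stopifnot(length(y) == length(x), length(tau) == 1L)
  if (!is.finite(tau) || tau <= 0 || tau >= 1) stop("tau must be in (0,1)")
  if (length(y) < 10L) stop("need at least 10 observations")
  if (anyNA(y) || anyNA(x)) stop("missing values in y or x")
  if (max(x) - min(x) <= 1e-12) stop("x is constant; slope undefined")
  rq_fit_cpp(as.numeric(y), as.numeric(x), tau)
}

# internal constructor; also the hook tests use to build toy profiles
new_slope_profile <- function(taus, slope, se, cov, ols_slope, ols_se,
                              ols_r2, n, B, seed, boot_slopes = NULL,
                              intercepts = NULL) {
  structure(list(taus = taus, percentile = 100 * taus, slope = slope,
                 se = se, cov = cov, ols_slope = ols_slope, ols_se = ols_se,
                 ols_r2 = ols_r2, n = n, B = B, seed = seed,
                 boot_slopes = boot_slopes, intercepts = intercepts),
            class = "qp_slope_profile")
}

#' Quantile-slope profile with paired-bootstrap covariance
#'
#' Fits the quantile regression slope of `y` on `x` at every grid quantile,
#' then estimates the standard errors and the full covariance matrix of the
#' slope vector by the paired bootstrap: subjects are resampled with
#' replacement and all quantiles are refitted on the same replicate (shared
#' indices across quantiles, as a valid cross-quantile covariance requires).
#' A standard least-squares fit of the same data is attached for comparison.
#'
#' @param y adjusted trait values.
#' @param x adjusted score values.
#' @param grid quantile levels from [quantile_grid()].
#' @param B bootstrap replicates; defaults to 1000. Values below 1000 warn
#'   (smaller B is intended for simulation loops); B < 50 is an error.
#' @param seed integer seed for the bootstrap stream.
#' @return object of class `qp_slope_profile`: per-quantile `slope` and
#'   bootstrap `se`, the `cov` matrix across the grid, `ols_slope`,
#'   `ols_se`, `ols_r2`, `n`, `B`, `seed`, and the raw bootstrap slope
#'   matrix.
#' @export
fit_profile <- function(y, x, grid = quantile_grid(), B = 1000L,
                        seed = 1L) {
  stopifnot(length(y) == length(x))
  keep <- !(is.na(y) | is.na(x))
  y <- as.numeric(y[keep]); x <- as.numeric(x[keep])
  n <- length(y)
  if (n < 10L) stop("need at least 10 complete observations")
  if (max(x) - min(x) <= 1e-12) stop("x is constant; profile undefined")
  if (any(diff(grid) <= 0) || any(grid <= 0 | grid >= 1))
    stop("grid must be strictly increasing within (0,1)")
  B <- as.integer(B)
  if (B < 50L) stop("B must be at least 50")
  if (B < 1000L)
    message("B = ", B, " bootstrap replicates (full-resolution default is 1000)")

  pt <- rq_grid_cpp(y, x, grid)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(split_seed(seed, "bootstrap"))
  # a replicate with constant x is redrawn; more than 1% redraws aborts
  boot <- rq_boot_cpp(y, x, grid, B, max_redraw = max(1L, as.integer(0.01 * B)))
  if (boot$redraws > 0)
    message(boot$redraws, " bootstrap replicate(s) redrawn (constant score)")
  S <- boot$slopes
  covm <- stats::cov(S)
  ols <- lm.fit(cbind(1, x), y)
  rss <- sum(ols$residuals^2)
  sxx <- sum((x - mean(x))^2)
  ols_se <- sqrt(rss / (n - 2) / sxx)
  ols_r2 <- 1 - rss / sum((y - mean(y))^2)
  new_slope_profile(taus = grid, slope = pt[, "slope"],
                    se = sqrt(diag(covm)), cov = covm,
                    ols_slope = unname(ols$coefficients[2L]),
                    ols_se = ols_se, ols_r2 = ols_r2,
                    n = n, B = B, seed = seed, boot_slopes = S,
                    intercepts = pt[, "intercept"])
}

#' @export
print.qp_slope_profile <- function(x, ...) {
  cat("Quantile-slope profile:", length(x$taus), "quantiles (",
      min(x$percentile), "-", max(x$percentile), "), n =", x$n,
      ", B =", x$B, "bootstrap replicates\n")
  cat(sprintf("  OLS slope %.4g (SE %.3g, R2 %.4g)\n",
              x$ols_slope, x$ols_se, x$ols_r2))
  ix <- round(seq(1, length(x$taus), length.out = min(5, length(x$taus))))
  cat("  slopes:", paste(sprintf("%g%%: %.4g±%.3g", x$percentile[ix],
                                 x$slope[ix], x$se[ix]), collapse = ", "),
      "\n")
  invisible(x)
}

# Project a symmetric matrix to the nearest positive semidefinite one by
# clipping negative eigenvalues.
.nearest_psd <- function(S, tol = 1e-10) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= -tol * max(abs(e$values), 1)) return(S)
  warning("covariance matrix not PSD; projecting to the nearest PSD matrix")
  v <- pmax(e$values, 0)
  e$vectors %*% (v * t(e$vectors))
}

#' Linear-contrast trend test across the quantile profile
#'
#' Tests whether the slopes increase or decrease with the percentile of the
#' phenotype via the linear contrast of the slopes over the grid. With
#' percentiles \eqn{k} and centered weights \eqn{c_k = k - \bar k}, the
#' estimate \eqn{\hat\delta = \sum c_k \hat\beta(k) / \sum c_k^2} is the
#' least-squares slope of the profile on the percentile (trait units per
#' score unit per percent), with variance \eqn{c'\Sigma c / (\sum c_k^2)^2}
#' propagated through the bootstrap covariance \eqn{\Sigma}. A
#' precision-weighted variant (weights proportional to inverse bootstrap
#' variance) is available via `weighting`.
#'
#' @param profile a `qp_slope_profile` with at least 3 grid points.
#' @param weighting `"equal"` (default, the canonical linear contrast) or
#'   `"precision"`.
#' @return object of class `qp_trend`: `delta` (slope increase per
#'   1-percentile increase), `se`, `z`, `p` (two-sided normal).
#' @export
trend_test <- function(profile, weighting = c("equal", "precision")) {
  stopifnot(inherits(profile, "qp_slope_profile"))
  weighting <- match.arg(weighting)
  k <- profile$percentile
  if (length(k) < 3L) stop("need at least 3 grid points")
  if (is.null(profile$cov)) stop("profile lacks a bootstrap covariance")
  S <- .nearest_psd(profile$cov)
  w <- if (weighting == "equal") rep(1, length(k)) else 1 / pmax(diag(S), 1e-300)
  kb <- sum(w * k) / sum(w)
  cc <- w * (k - kb)
  den <- sum(cc * k)
  delta <- sum(cc * profile$slope) / den
  v <- drop(t(cc) %*% S %*% cc) / den^2
  se <- sqrt(v)
  z <- delta / se
  structure(list(delta = delta, se = se, z = z,
                 p = 2 * pnorm(-abs(z)), weighting = weighting),
            class = "qp_trend")
}

#' @export
print.qp_trend <- function(x, ...) {
  cat(sprintf(
    "Trend: %.4g ± %.3g per 1-percentile increase (z = %.3g, P = %.3g)\n",
    x$delta, x$se, x$z, x$p))
  invisible(x)
}

#' Interpolated slope at a (possibly noninteger) percentile
#'
#' Linear interpolation between adjacent grid percentiles; percentiles
#' outside the grid are clamped to the boundary slope.
#'
#' @param profile a `qp_slope_profile`.
#' @param p percentile(s) in \[0, 100\].
#' @return interpolated slope(s).
#' @export
slope_at <- function(profile, p) {
  stopifnot(inherits(profile, "qp_slope_profile"), all(p >= 0 & p <= 100))
  approx(profile$percentile, profile$slope, xout = p, rule = 2)$y
}

#' Fold ratio and absolute difference between two percentile slopes
#'
#' @param profile a `qp_slope_profile`.
#' @param p_low,p_high percentiles to compare (default 10 and 90).
#' @return list with `ratio` (`NA` with a warning when the low slope is
#'   zero), `difference`, and the two slopes.
#' @export
fold_ratio <- function(profile, p_low = 10, p_high = 90) {
  lo <- slope_at(profile, p_low)
  hi <- slope_at(profile, p_high)
  ratio <- if (abs(lo) < 1e-300) {
    warning("slope at the low percentile is zero; ratio undefined")
    NA_real_
  } else hi / lo
  list(ratio = ratio, difference = hi - lo, slope_low = lo, slope_high = hi)
}

#' Range of percentiles covered by the OLS confidence interval
#'
#' Finds the contiguous grid range whose quantile slopes lie inside the 95%
#' confidence interval of the standard regression slope
#' (OLS slope ± 1.96 SE), and the fraction of the grid outside it. A
#' profile that fans out with the percentile leaves the OLS interval at
#' both ends, so the interval "misrepresents" that fraction of the
#' distribution.
#'
#' @param profile a `qp_slope_profile`.
#' @return list `low`, `high` (percentiles bounding the longest contiguous
#'   in-interval run; `NA` if no grid slope is inside), and
#'   `fraction_outside`.
#' @export
ci_coverage_band <- function(profile) {
  stopifnot(inherits(profile, "qp_slope_profile"))
  lo <- profile$ols_slope - 1.96 * profile$ols_se
  hi <- profile$ols_slope + 1.96 * profile$ols_se
  inside <- profile$slope >= lo & profile$slope <= hi
  if (!any(inside))
    return(list(low = NA_real_, high = NA_real_, fraction_outside = 1))
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- starts[best]:ends[best]
  list(low = profile$percentile[starts[best]],
       high = profile$percentile[ends[best]],
       fraction_outside = 1 - length(idx) / length(inside))
}
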