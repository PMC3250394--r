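#' Residual-permutation null check
#'
#' Artifact control for the quantile-slope trend: fit the standard
#' regression of `y` on `x`, then randomly permute the residuals across the
#' fitted values. The permuted response has, by construction, the same
#' slope at every quantile (parallel quantile lines), so any trend detected
#' on it is an artifact of skewness or other distributional features rather
#' than genuine quantile dependence. The profile + trend test is rerun on
#' each permuted response and the rejection fraction at 0.05 reported; it
#' should match the nominal level.
#'
#' @param y adjusted trait values.
#' @param x adjusted score values.
#' @param grid quantile grid; defaults to the reduced 5-percent-step grid
#'   for tractability inside the permutation loop.
#' @param B_boot bootstrap replicates per permutation (default 200).
#' @param n_perm number of permutations (>= 20; default 200).
#' @param seed integer seed.
#' @return object of class `qp_perm_null`: `n_perm`, per-permutation
#'   `delta` and `p`, `rejection_fraction` at 0.05, `seed`.
#' @export
permutation_null <- function(y, x, grid = quantile_grid(step = 5),
                             B_boot = 200L, n_perm = 200L, seed = 1L) {
  stopifnot(length(y) == length(x))
  if (n_perm < 20L) stop("n_perm must be at least 20")
  fit <- lm.fit(cbind(1, x), as.numeric(y))
  fv <- fit$fitted.values
  res <- fit$residuals
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(split_seed(seed, "permutation"))
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  delta <- p <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    y_perm <- fv + sample(res)
    prof <- suppressMessages(
      fit_profile(y_perm, x, grid = grid, B = B_boot, seed = perm_seeds[i]))
    tr <- trend_test(prof)
    delta[i] <- tr$delta
    p[i] <- tr$p
  }
  structure(list(n_perm = n_perm, delta = delta, p = p,
                 rejection_fraction = mean(p < 0.05), seed = seed),
            class = "qp_perm_null")
}

#' @export
print.qp_perm_null <- function(x, ...) {
  cat(sprintf(
    "Residual-permutation null: %d permutations, rejection fraction at 0.05 = %.3f (mean delta %.3g)\n",
    x$n_perm, x$rejection_fraction, mean(x$delta)))
  invisible(x)
}

#' Contrast of two percentile slopes against the standard regression slope
#'
#' Direct arithmetic used in reporting: the fold ratio between the slopes,
#' their absolute difference, and the difference expressed as a percentage
#' of the standard least-squares slope (values above 100 mean the
#' difference exceeds the standard slope itself).
#'
#' @param slope_low,slope_high slopes at the lower/upper percentile.
#' @param ols_slope standard least-squares slope.
#' @return list `ratio`, `difference`, `pct_of_ols`.
#' @export
slope_contrast_summary <- function(slope_low, slope_high, ols_slope) {
  list(ratio = slope_high / slope_low,
       difference = slope_high - slope_low,
       pct_of_ols = 100 * (slope_high - slope_low) / ols_slope)
}

#' Summary table of slope profiles at reference percentiles
#'
#' One row per trait: quantile-regression slope ± bootstrap SE at the
#' reference percentiles, the standard least-squares column, the 90th/10th
#' fold ratio, the absolute slope difference, and the difference as a
#' percent of the least-squares slope. Values are pure functions of the
#' profiles; formatting is 2-decimal.
#'
#' @param profiles named list of `qp_slope_profile` objects (names = trait
#'   labels).
#' @param percentiles reference percentiles (default 10, 25, 50, 75, 90).
#' @return data.frame; the formatted `slope ± SE` strings plus numeric
#'   `fold_ratio_90_10`, `difference_90_10`, `pct_of_ols` columns.
#' @export
summary_table <- function(profiles, percentiles = c(10, 25, 50, 75, 90)) {
  stopifnot(length(profiles) >= 1)
  if (is.null(names(profiles)))
    names(profiles) <- paste0("trait", seq_along(profiles))
  rows <- lapply(names(profiles), function(nm) {
    pr <- profiles[[nm]]
    sl <- slope_at(pr, percentiles)
    se <- approx(pr$percentile, pr$se, xout = percentiles, rule = 2)$y
    cells <- sprintf("%.2f±%.2f", sl, se)
    fr <- fold_ratio(pr, 10, 90)
    ctr <- slope_contrast_summary(fr$slope_low, fr$slope_high, pr$ols_slope)
    out <- data.frame(trait = nm, t(cells),
                      ols = sprintf("%.2f±%.2f", pr$ols_slope, pr$ols_se),
                      fold_ratio_90_10 = fr$ratio,
                      difference_90_10 = fr$difference,
                      pct_of_ols = ctr$pct_of_ols,
                      stringsAsFactors = FALSE)
    names(out)[2:(1 + length(percentiles))] <- paste0("p", percentiles)
    out
  })
  do.call(rbind, rows)
}
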