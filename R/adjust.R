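#' Residualize a trait or score on the standard covariate set
#'
#' Returns least-squares residuals from the design
#' \[intercept, sex, age, age^2, study indicators, smoking\] — the covariate
#' set used for both phenotypes and risk scores before quantile profiling.
#' Residuals are mean-zero and orthogonal to every design column.
#'
#' @param values numeric vector (trait or score units).
#' @param covariates data.frame with columns `sex` (binary), `age` (years),
#'   `study` (categorical), `smoking` (binary). Rows with missing covariates
#'   are dropped pairwise with a message; the result keeps `NA` at those
#'   positions.
#' @return numeric vector of residuals with attribute `design` describing
#'   the columns used.
#' @export
adjust_covariates <- function(values, covariates) {
  need <- c("sex", "age", "study", "smoking")
  if (!all(need %in% names(covariates)))
    stop("covariates must have columns: ", paste(need, collapse = ", "))
  if (length(values) != nrow(covariates))
    stop("values and covariates disagree on the number of subjects")
  cc <- stats::complete.cases(covariates[need]) & !is.na(values)
  if (!all(cc))
    message("dropping ", sum(!cc), " rows with missing covariates or values")
  cv <- covariates[cc, , drop = FALSE]
  X <- model.matrix(~ sex + age + I(age^2) + factor(study) + smoking,
                    data = cv)
  const <- apply(X[, -1L, drop = FALSE], 2L, function(col) sd(col) == 0)
  if (any(const)) {
    warning("dropping constant design column(s): ",
            paste(names(const)[const], collapse = ", "))
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  if (sum(cc) <= ncol(X))
    stop("not enough subjects (", sum(cc), ") for ", ncol(X),
         " design columns")
  res <- rep(NA_real_, length(values))
  res[cc] <- lm.fit(X, values[cc])$residuals
  attr(res, "design") <- colnames(X)
  res
}

#' Standardize height to a z-score within sex
#'
#' \eqn{z = (h - \bar h_{sex}) / \mathrm{sd}_{sex}(h)}, using the sample SD
#' (n-1 denominator), computed within each sex stratum.
#'
#' @param height numeric heights (cm).
#' @param sex binary stratum indicator.
#' @return z-scores, one per subject.
#' @export
standardize_height <- function(height, sex) {
  stopifnot(length(height) == length(sex))
  z <- rep(NA_real_, length(height))
  for (s in unique(sex)) {
    i <- which(sex == s)
    if (length(i) < 2L)
      stop("sex stratum ", s, " has fewer than 2 subjects")
    sdev <- sd(height[i])
    if (sdev == 0) stop("zero height SD in sex stratum ", s)
    z[i] <- (height[i] - mean(height[i])) / sdev
  }
  z
}
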