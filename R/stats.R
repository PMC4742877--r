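# Standardization, multiple regression with standardized betas and partial
# correlations, and simple correlation helpers for the brain-behavior
# analyses.

#' Standardize a column to mean 0, SD 1
#'
#' Uses the sample (n-1) standard deviation.  Missing values are ignored
#' for the mean/SD and propagated in the output.
#'
#' @param x Numeric vector with at least 2 non-missing values.
#' @return The z-scored vector.
#' @export
standardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  s <- stats::sd(x[ok])
  if (s == 0) stop("zero variance: cannot standardize a constant column")
  (x - mean(x[ok])) / s
}

#' Multiple linear regression with standardized betas
#'
#' Ordinary least squares of `response` on `predictors`, reporting the
#' model R-squared and adjusted R-squared (the correction for the number
#' of predictors), the overall F test, per-predictor standardized betas
#' with their p-values, and partial correlations.  Standardized betas are
#' the coefficients of the same model fit on z-scored response and
#' predictors; partial correlations are computed from the residuals of
#' each predictor and the response against the remaining predictors
#' (`partial = "semi"` gives semi-partial correlations, residualizing the
#' predictor only).  Rows with missing values are dropped listwise.
#'
#' @param data A data frame.
#' @param response Name of the dependent variable.
#' @param predictors Character vector of predictor names.
#' @param partial "full" (default) or "semi".
#' @return A list of class `regression_result`: `r_squared`,
#'   `adj_r_squared`, `f_stat`, `df` (c(df1, df2)), `p_value`, `n`, and
#'   `coefficients` (data frame: `predictor`, `beta`, `se`, `t`, `p`,
#'   `partial_r`).
#' @export
multiple_regression <- function(data, response, predictors,
                                partial = c("full", "semi")) {
  partial <- match.arg(partial)
  stopifnot(is.data.frame(data), response %in% names(data),
            all(predictors %in% names(data)))
  d <- data[, c(response, predictors), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  k <- length(predictors)
  if (n < k + 2L) stop("insufficient sample size for the number of predictors")
  dz <- as.data.frame(lapply(d, standardize))
  qrX <- qr(as.matrix(cbind(1, dz[predictors])))
  if (qrX$rank < k + 1L) stop("rank-deficient design matrix")
  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  fitz <- stats::lm(fml, data = dz)
  sm <- summary(fit)
  smz <- summary(fitz)
  partial_r <- vapply(predictors, function(p) {
    others <- setdiff(predictors, p)
    rx <- if (length(others)) {
      stats::resid(stats::lm(stats::reformulate(others, response = p), data = d))
    } else d[[p]]
    ry <- if (partial == "full" && length(others)) {
      stats::resid(stats::lm(stats::reformulate(others, response = response),
                             data = d))
    } else d[[response]]
    stats::cor(rx, ry)
  }, numeric(1))
  coefs <- data.frame(
    predictor = predictors,
    beta = unname(stats::coef(fitz)[predictors]),
    se = smz$coefficients[predictors, "Std. Error"],
    t = smz$coefficients[predictors, "t value"],
    p = smz$coefficients[predictors, "Pr(>|t|)"],
    partial_r = unname(partial_r),
    row.names = NULL
  )
  f <- sm$fstatistic
  structure(
    list(r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared,
         f_stat = unname(f[1]), df = unname(f[2:3]),
         p_value = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)),
         n = n, coefficients = coefs, fit = fit),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result: R^2 = %.3f (adj %.3f), F(%d,%d) = %.2f, p = %.4g, n = %d>\n",
              x$r_squared, x$adj_r_squared, x$df[1], x$df[2], x$f_stat,
              x$p_value, x$n))
  df <- x$coefficients
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-22s Beta = %+6.3f  p = %.4g  partial r = %+6.3f\n",
                df$predictor[i], df$beta[i], df$p[i], df$partial_r[i]))
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L) stop("need at least 3 paired values")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) stop("zero variance")
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
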