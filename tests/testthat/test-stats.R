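# Standardization, OLS with standardized betas, correlations.

# brute-force normal-equations oracle: betahat = (X'X)^-1 X'y
ols_oracle <- function(y, X) {
  Xd <- cbind(1, as.matrix(X))
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  yhat <- Xd %*% beta
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(beta = as.numeric(beta), r2 = 1 - ss_res / ss_tot)
}

# fixed 10-row fixture used by the oracle comparisons
stats_fixture <- function() {
  data.frame(
    y  = c(2.3, 1.1, 4.5, 3.2, 5.6, 2.9, 4.1, 0.7, 3.8, 5.0),
    x1 = c(0.5, 0.1, 1.2, 0.8, 1.6, 0.7, 1.1, 0.0, 0.9, 1.4),
    x2 = c(10, 14, 8, 11, 6, 12, 9, 15, 10, 7)
  )
}

test_that("standardize gives mean 0, sample SD 1", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(c(5, 2, 9, 4, 8))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  zm <- standardize(c(1, NA, 3))
  expect_true(is.na(zm[2]))
  expect_error(standardize(rep(4, 6)), "variance")
  expect_error(standardize(c(1, NA, NA)))
})

test_that("regression matches the normal-equations oracle to 1e-10", {
  d <- stats_fixture()
  fit <- multiple_regression(d, "y", c("x1", "x2"))
  orc <- ols_oracle(d$y, d[, c("x1", "x2")])
  expect_equal(fit$r_squared, orc$r2, tolerance = 1e-10)
  # standardized betas equal the oracle on z-scored columns
  dz <- as.data.frame(lapply(d, standardize))
  orcz <- ols_oracle(dz$y, dz[, c("x1", "x2")])
  expect_equal(fit$coefficients$beta, orcz$beta[-1], tolerance = 1e-10)
  expect_equal(fit$df, c(2, 7))
  # F statistic from its definition
  k <- 2; n <- 10
  f_manual <- (orc$r2 / k) / ((1 - orc$r2) / (n - k - 1))
  expect_equal(fit$f_stat, f_manual, tolerance = 1e-10)
})

test_that("a perfectly predictive regressor gives R^2 = 1 and beta = 1", {
  d <- data.frame(y = c(1, 3, 2, 5, 4, 6), x = c(1, 3, 2, 5, 4, 6) * 2 + 7)
  # summary.lm warns about the perfect fit; the fit itself is what is tested
  fit <- suppressWarnings(multiple_regression(d, "y", "x"))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$coefficients$beta, 1)
  expect_equal(fit$coefficients$partial_r, 1)
})

test_that("regression guards its preconditions", {
  d <- stats_fixture()
  d$x3 <- 2 * d$x1 + 1  # collinear
  expect_error(multiple_regression(d, "y", c("x1", "x3")), "rank-deficient")
  expect_error(multiple_regression(d[1:3, ], "y", c("x1", "x2")),
               "insufficient")
})

test_that("standardized betas are invariant under affine predictor rescaling", {
  d <- stats_fixture()
  base <- multiple_regression(d, "y", c("x1", "x2"))
  set.seed(11)
  for (i in 1:5) {
    d2 <- d
    a <- runif(1, 0.1, 50); b <- runif(1, -10, 10)
    d2$x1 <- a * d2$x1 + b
    fit2 <- multiple_regression(d2, "y", c("x1", "x2"))
    expect_equal(fit2$coefficients$beta, base$coefficients$beta,
                 tolerance = 1e-10)
    expect_equal(fit2$r_squared, base$r_squared, tolerance = 1e-10)
  }
})

test_that("partial correlations agree with the residual-based definition", {
  d <- stats_fixture()
  fit <- multiple_regression(d, "y", c("x1", "x2"))
  r_manual <- cor(resid(lm(x1 ~ x2, d)), resid(lm(y ~ x2, d)))
  expect_equal(fit$coefficients$partial_r[1], r_manual, tolerance = 1e-12)
  semi <- multiple_regression(d, "y", c("x1", "x2"), partial = "semi")
  r_semi <- cor(resid(lm(x1 ~ x2, d)), d$y)
  expect_equal(semi$coefficients$partial_r[1], r_semi, tolerance = 1e-12)
})

test_that("independent noise yields near-zero R^2 at large n", {
  set.seed(3)
  reps <- sapply(1:20, function(i) {
    d <- data.frame(y = rnorm(1000), x1 = rnorm(1000), x2 = rnorm(1000))
    fit <- multiple_regression(d, "y", c("x1", "x2"))
    c(fit$r_squared, fit$p_value)
  })
  expect_lt(mean(reps[1, ]), 0.01)
  expect_gt(mean(reps[2, ] > 0.05), 0.8)
})

test_that("pearson correlation handles the degenerate sign cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_equal(pearson_correlation(c(0, 1, 2), c(1, 0.5, 0))$r, -1)
  expect_error(pearson_correlation(c(0, 1), c(1, 0)))
  expect_error(pearson_correlation(x, rep(1, 4)), "variance")
})
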