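test_that("OLS interpolates a noiseless linear truth and recovers weights", {
  sim <- simulate_regression_cohort(120, 15, n_active = 4, r2 = 1, seed = 2)
  fit <- fit_ols(sim$X, sim$y)
  expect_lt(max(abs(predict(fit, sim$X) - sim$y)), 1e-8)
  cf <- coef(fit)
  expect_lt(max(abs(cf$weights - sim$w_true)), 1e-6)
  expect_equal(cf$intercept, sim$bias, tolerance = 1e-8)
})

test_that("a constant design collapses to the mean predictor", {
  X <- matrix(1, 10, 1)
  y <- rnorm(10, 5)
  fit <- fit_ols(X, y)
  expect_equal(unname(fit$weights), 0)
  expect_equal(fit$bias, mean(y))
  expect_equal(unname(predict(fit, X)), rep(mean(y), 10))
})

test_that("underdetermined OLS warns and returns the minimum-norm solution", {
  sim <- simulate_regression_cohort(20, 40, 3, r2 = 1, seed = 6)
  expect_warning(fit <- fit_ols(sim$X, sim$y), "minimum-norm")
  expect_true(fit$min_norm)
  # an exact interpolator despite rank deficiency
  expect_lt(max(abs(predict(fit, sim$X) - sim$y)), 1e-8)
})

test_that("OLS residuals are orthogonal to the standardized design", {
  sim <- simulate_regression_cohort(150, 12, 4, r2 = 0.6, seed = 8)
  fit <- fit_ols(sim$X, sim$y)
  res <- sim$y - predict(fit, sim$X)
  Xs <- scale(sim$X, center = fit$center, scale = fit$scale)
  expect_lt(max(abs(crossprod(Xs, res))), 1e-8)
})

test_that("scaling the response scales OLS weights and bias linearly", {
  sim <- simulate_regression_cohort(80, 8, 3, r2 = 0.7, seed = 10)
  f1 <- fit_ols(sim$X, sim$y)
  f2 <- fit_ols(sim$X, 3.5 * sim$y)
  expect_equal(f2$weights, 3.5 * f1$weights, tolerance = 1e-10)
  expect_equal(f2$bias, 3.5 * f1$bias, tolerance = 1e-10)
})

test_that("the penalty-free LASSO limit matches OLS", {
  sim <- simulate_regression_cohort(200, 20, 3, r2 = 0.8, seed = 5)
  o <- fit_ols(sim$X, sim$y)
  l0 <- fit_lasso(sim$X, sim$y, 0)
  expect_lt(max(abs(o$weights - l0$weights)), 1e-5)
  expect_equal(o$bias, l0$bias)
})

test_that("penalties at or above the null bound zero every weight exactly", {
  sim <- simulate_regression_cohort(100, 25, 4, r2 = 0.6, seed = 13)
  lmax <- lasso_lambda_max(sim$X, sim$y)
  for (lam in c(lmax, lmax * 1.3)) {
    fit <- fit_lasso(sim$X, sim$y, lam)
    expect_identical(unname(fit$weights), rep(0, 25))
    expect_equal(fit$bias, mean(sim$y))
  }
  # just below the bound at least one weight activates
  below <- fit_lasso(sim$X, sim$y, lmax * 0.99)
  expect_gt(sum(below$weights != 0), 0)
})

test_that("support size is non-increasing along a descending penalty path", {
  sim <- simulate_regression_cohort(150, 30, 5, r2 = 0.6, seed = 14)
  grid <- default_lambda_grid(sim$X, sim$y, length = 12)
  w <- NULL
  nnz_desc <- integer(0)
  for (lam in sort(grid, decreasing = TRUE)) {
    fit <- fit_lasso(sim$X, sim$y, lam, w_init = w)
    w <- fit$weights
    nnz_desc <- c(nnz_desc, sum(w != 0))
  }
  expect_true(all(diff(nnz_desc) >= 0))  # descending lambda -> growing support
})

test_that("coordinate descent agrees with glmnet at tight tolerance", {
  skip_if_not_installed("glmnet")
  sim <- simulate_regression_cohort(180, 25, 5, r2 = 0.7, seed = 15)
  for (lam in c(0.4, 0.1, 0.02)) {
    mine <- coef(fit_lasso(sim$X, sim$y, lam, tol = 1e-9))
    ref <- glmnet::glmnet(sim$X, sim$y, lambda = lam, standardize = TRUE,
                          thresh = 1e-14)
    ref_coef <- as.numeric(stats::coef(ref))
    expect_equal(unname(mine$weights), ref_coef[-1], tolerance = 1e-6)
    expect_equal(mine$intercept, ref_coef[1], tolerance = 1e-6)
  }
})

test_that("the penalized objective never increases across sweeps", {
  sim <- simulate_regression_cohort(120, 40, 5, r2 = 0.5, seed = 16)
  fit <- fit_lasso(sim$X, sim$y, 0.05, trace = TRUE, w_init = numeric(40))
  tr <- fit$objective_trace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("penalty selection is seeded, tie-stable and case-aware", {
  sim <- simulate_regression_cohort(90, 10, 3, r2 = 0.7, seed = 18)
  # single-element grid is a forced choice
  one <- select_lambda(sim$X, sim$y, 0.2, seed = 1)
  expect_equal(one$lambda, 0.2)
  # duplicated grid values: deterministic first-index tie-break
  two <- select_lambda(sim$X, sim$y, c(0.2, 0.2), seed = 1)
  expect_equal(two$lambda, 0.2)
  expect_equal(unname(two$cv_mse[1]), unname(two$cv_mse[2]))

  sel1 <- select_lambda(sim$X, sim$y, c(0.5, 0.1, 0.02), seed = 4)
  sel2 <- select_lambda(sim$X, sim$y, c(0.5, 0.1, 0.02), seed = 4)
  expect_identical(sel1, sel2)

  # both rows of a case share a fold
  ids <- rep(1:45, 2)
  sel <- select_lambda(sim$X, sim$y, c(0.3, 0.05), seed = 2, case_ids = ids)
  expect_equal(sel$folds[1:45], sel$folds[46:90])

  expect_error(select_lambda(sim$X, sim$y, numeric(0)), "lambda_grid")
  expect_error(select_lambda(sim$X[1:6, ], sim$y[1:6], 0.1, k_folds = 5),
               "fold")
})

test_that("cross-validated penalty choice keeps a planted sparse support", {
  sim <- simulate_regression_cohort(300, 45, n_active = 3, r2 = 0.75, seed = 19)
  sel <- select_lambda(sim$X, sim$y, default_lambda_grid(sim$X, sim$y), seed = 19)
  fit <- fit_lasso(sim$X, sim$y, sel$lambda)
  expect_true(all(which(sim$w_true != 0) %in% which(fit$weights != 0)))
})

test_that("models round-trip through JSON with bit-identical predictions", {
  sim <- simulate_regression_cohort(60, 12, 3, r2 = 0.8, seed = 20)
  fit <- fit_lasso(sim$X, sim$y, 0.1, target_name = "lumbar_bmd")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_identical(predict(back, sim$X), predict(fit, sim$X))
  expect_equal(back$lambda, fit$lambda)
  expect_equal(back$target_name, "lumbar_bmd")
  expect_error(predict(back, sim$X[, 1:5]), "mismatch")
})

test_that("parameter recovery sharpens as the cohort grows", {
  err_at_n <- function(n, seed) {
    sim <- simulate_regression_cohort(n, 90, 5, r2 = 0.5, seed = seed)
    fit <- fit_ols(sim$X, sim$y)
    median(abs(coef(fit)$weights - sim$w_true))
  }
  seeds <- 1:20
  err_small <- vapply(seeds, function(s) err_at_n(395, s), numeric(1))
  err_large <- vapply(seeds + 100, function(s) err_at_n(790, s), numeric(1))
  expect_lt(median(err_large), median(err_small))
})
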