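test_that("preprocessing standardizes, flags skew and drops constants", {
  set.seed(5)
  X <- cbind(sym = rnorm(300), ln = exp(rnorm(300)), flat = rep(2, 300))
  expect_warning(Z <- preprocess_predictors(X), "zero-variance")
  expect_identical(colnames(Z), c("sym", "ln"))
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1))
  expect_identical(attr(Z, "flagged"), "ln") # lognormal skew ~ 6.2 >= 0.7
  expect_lt(abs(attr(Z, "skewness")[["sym"]]), 0.7)
  # the fitted transform applies unchanged to new rows
  Znew <- faceerp:::apply_preprocess(X[1:5, c("sym", "ln")], Z)
  expect_equal(unclass(Znew), unclass(Z[1:5, ]), ignore_attr = TRUE)
})

test_that("the unpenalized limit matches ordinary least squares", {
  set.seed(11)
  X <- scale(matrix(rnorm(60 * 8), 60))
  y <- drop(X[, 1] * 0.8 - X[, 2] * 0.5 + rnorm(60))
  fit <- fit_elastic_net(X, y, lambda = 0, alpha = 1, tol = 1e-9)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(fit$beta), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-8)
})

test_that("the orthonormal-design lasso is exact soft-thresholding", {
  set.seed(12)
  n <- 60; p <- 8
  Xc <- scale(matrix(rnorm(n * p), n), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Xc)) * sqrt(n) # centered columns, crossprod(Q)/n = I
  y <- drop(Q[, 1] * 0.6 - Q[, 2] * 0.3 + rnorm(n))
  b_ols <- drop(crossprod(Q, y)) / n
  lam <- 0.1
  fit <- fit_elastic_net(Q, y, lambda = lam, alpha = 1, tol = 1e-10)
  expect_equal(unname(fit$beta),
               sign(b_ols) * pmax(abs(b_ols) - lam, 0), tolerance = 1e-8)
})

test_that("full shrinkage, monotone objective and KKT optimality hold", {
  set.seed(13)
  X <- scale(matrix(rnorm(50 * 6), 50))
  y <- rnorm(50, 3)
  fit <- fit_elastic_net(X, y, lambda = 1e5, alpha = 0.5)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, mean(y))

  fit2 <- fit_elastic_net(X, y + X[, 1], lambda = 0.05, alpha = 0.7,
                          tol = 1e-10)
  expect_true(all(diff(fit2$objective) <= 1e-12))
  expect_lt(fit2$kkt, 1e-8)

  # independent implementation agreement (same objective parameterization)
  skip_if_not_installed("glmnet")
  al <- 0.6
  lams <- lambda_grid(X, y + X[, 1], alpha = al, n = 30)
  gl <- glmnet::glmnet(X, y + X[, 1], alpha = al, lambda = lams,
                       standardize = FALSE, thresh = 1e-12)
  mine <- fit_elastic_net(X, y + X[, 1], lambda = lams[15], alpha = al,
                          tol = 1e-10)
  expect_equal(unname(mine$beta), unname(as.numeric(coef(gl)[-1, 15])),
               tolerance = 0.02)
})

test_that("lambda_max zeroes every coefficient and the grid spans 4 decades", {
  set.seed(14)
  X <- scale(matrix(rnorm(80 * 5), 80))
  y <- drop(X %*% c(1, -1, 0, 0, 0) + rnorm(80))
  g <- lambda_grid(X, y, alpha = 1, n = 50)
  expect_length(g, 50)
  expect_equal(log10(g[1] / g[50]), 4, tolerance = 1e-9)
  fit <- fit_elastic_net(X, y, lambda = g[1], alpha = 1)
  expect_true(all(fit$beta == 0))
  fit2 <- fit_elastic_net(X, y, lambda = g[1] * 0.9, alpha = 1)
  expect_true(any(fit2$beta != 0))
})

test_that("nested cross-validation recovers a near-noiseless signal", {
  set.seed(15)
  n <- 40; p <- 6
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
  beta <- c(1, -1, 0.8, 0, 0, 0)
  y <- drop(X %*% beta) + rnorm(n, 0, 0.02)
  rep <- nested_cv_enet(X, y, alphas = c(0.5, 1), nlambda = 20,
                        inner_k = 10, inner_reps = 2, n_boot = 200, seed = 3)
  expect_gt(rep$pearson_r, 0.99)
  expect_true(all(paste0("f", 1:3) %in% rep$always_selected$feature))
  expect_identical(sign(rep$always_selected$mean[
    match(paste0("f", 1:3), rep$always_selected$feature)]), c(1, -1, 1))
  # definitional identities
  expect_equal(rep$relative_error, rep$rmse / (max(y) - min(y)))
  expect_equal(rep$rmse, sqrt(mean((rep$observed - rep$predicted)^2)))
  expect_true(rep$rmse >= rep$rmse_ci[1] - 1e-9 &&
              rep$rmse <= rep$rmse_ci[2] + 1e-9)
})

test_that("selection stability enforces the strict always-selected rule", {
  coefs <- cbind(a = c(1, 1, 1), b = c(1, 0, 1), c = c(-2, -2, -2))
  out <- selection_stability(coefs)
  expect_identical(out$feature, c("a", "c"))
  expect_equal(out$mean, c(1, -2))
  expect_equal(out$sd, c(0, 0))
})
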