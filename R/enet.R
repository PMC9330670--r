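#' Predictor preprocessing: skewness check and standardization
#'
#' Sample skewness is computed per predictor; any predictor with
#' `|skewness| >= 0.7` is flagged and transformed by `log1p` after shifting
#' to positive support, then all predictors are standardized to mean 0,
#' SD 1. Zero-variance predictors are dropped with a warning.
#'
#' @param X numeric predictor matrix.
#' @param skew_threshold flag threshold (default 0.7).
#' @param transform transform flagged predictors (default TRUE).
#' @return Standardized matrix with attributes `flagged` (names of skewed
#'   predictors), `center`, `scale`.
#' @export
preprocess_predictors <- function(X, skew_threshold = 0.7, transform = TRUE) {
  X <- as.matrix(X)
  sds <- apply(X, 2, sd)
  if (any(sds == 0 | !is.finite(sds))) {
    drop_cols <- which(sds == 0 | !is.finite(sds))
    warning("dropping zero-variance predictors: ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
  }
  sk <- apply(X, 2, e1071::skewness, type = 2)
  flagged <- colnames(X)[abs(sk) >= skew_threshold]
  shifts <- NULL
  if (transform && length(flagged)) {
    shifts <- setNames(numeric(length(flagged)), flagged)
    for (nm in flagged) {
      x <- X[, nm]
      shifts[nm] <- min(x)
      X[, nm] <- log1p(x - min(x))
    }
  }
  Xs <- standardize_cols(X)
  attr(Xs, "flagged") <- flagged
  attr(Xs, "skewness") <- sk
  attr(Xs, "shifts") <- shifts
  Xs
}

# apply a fitted preprocessing (transform + standardization) to new rows
apply_preprocess <- function(newdata, fitted) {
  newdata <- as.matrix(newdata)[, colnames(fitted), drop = FALSE]
  shifts <- attr(fitted, "shifts")
  for (nm in names(shifts)) {
    newdata[, nm] <- log1p(pmax(newdata[, nm] - shifts[nm], 0))
  }
  standardize_cols(newdata, center = attr(fitted, "center"),
                   scale = attr(fitted, "scale"))
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

enet_objective <- function(X, y, beta, intercept, lambda, alpha) {
  r <- y - intercept - drop(X %*% beta)
  sum(r^2) / (2 * length(y)) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' Elastic-net linear regression by coordinate descent
#'
#' Minimizes `(1/(2n)) * sum((y - b0 - X beta)^2) + lambda * (alpha *
#' sum(|beta|) + (1 - alpha)/2 * sum(beta^2))` by cyclic coordinate descent
#' with the soft-threshold update. Converges when the largest coefficient
#' change in a sweep falls below `tol`. The objective trace (one value per
#' sweep) is returned so monotone descent is checkable.
#'
#' @param X predictor matrix (standardized predictors recommended).
#' @param y response.
#' @param lambda penalty weight (>= 0).
#' @param alpha L1 mixing in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param tol coefficient-change tolerance (default 1e-7).
#' @param max_iter maximum sweeps (default 10000).
#' @param beta_init optional warm start.
#' @return `enet_fit`: `beta`, `intercept`, `lambda`, `alpha`, `objective`
#'   (per-sweep trace), `converged`, `kkt` (max KKT residual).
#' @export
fit_elastic_net <- function(X, y, lambda, alpha = 0.5, tol = 1e-7,
                            max_iter = 10000, beta_init = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 2, lambda >= 0, alpha >= 0, alpha <= 1)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  beta0 <- if (is.null(beta_init)) rep(0, p) else unname(beta_init)
  sol <- enet_cd(Xc, yc, lambda, alpha, tol, as.integer(max_iter), beta0)
  beta <- sol$beta
  obj <- sol$objective
  converged <- sol$converged
  if (!converged) warning("coordinate descent did not converge")
  r <- yc - drop(Xc %*% beta)
  # KKT residuals: grad_j + lambda*(1-alpha)*beta_j in lambda*alpha*[subgrad]
  g <- -drop(crossprod(Xc, r)) / n + lambda * (1 - alpha) * beta
  kkt <- max(ifelse(beta != 0, abs(g + lambda * alpha * sign(beta)),
                    pmax(abs(g) - lambda * alpha, 0)), 0)
  intercept <- ym - sum(xm * beta)
  structure(list(beta = setNames(beta, colnames(X)), intercept = intercept,
                 lambda = lambda, alpha = alpha, objective = obj,
                 converged = converged, kkt = kkt),
            class = "enet_fit")
}

#' @rdname fit_elastic_net
#' @param object an `enet_fit`.
#' @param newdata predictor matrix.
#' @param ... unused.
#' @export
predict.enet_fit <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$beta) + object$intercept
}

#' Penalty grid
#'
#' Log-spaced grid of `n` lambda values from `lambda_max` (the smallest
#' penalty that zeroes every coefficient, `max|X'y| / (n alpha)`) down by
#' `decades` decades.
#'
#' @param X,y data (X centered internally).
#' @param alpha L1 mixing (values < 0.001 are floored for the grid anchor).
#' @param n grid size (default 50).
#' @param decades span below `lambda_max` (default 4).
#' @return Decreasing numeric vector.
#' @export
lambda_grid <- function(X, y, alpha = 1, n = 50, decades = 4) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(Xc, yc))) / (nrow(X) * max(alpha, 1e-3))
  lmax <- lmax * (1 + 1e-6) # keep the top of the grid strictly all-zero
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = n))
}

# fit a warm-started path over a decreasing lambda grid; returns list of fits
enet_path <- function(X, y, lambdas, alpha, tol = 1e-7, max_iter = 10000) {
  beta <- NULL
  fits <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    fits[[i]] <- fit_elastic_net(X, y, lambdas[i], alpha, tol, max_iter,
                                 beta_init = beta)
    beta <- fits[[i]]$beta
  }
  fits
}

# repeated k-fold CV over the (lambda, alpha) grid; returns RMSE-minimizing pair
cv_choose_enet <- function(X, y, alphas, nlambda = 50, k = 10, reps = 10,
                           seed = 1, decades = 4) {
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(seed)
  best <- list(rmse = Inf, lambda = NA, alpha = NA)
  for (alpha in alphas) {
    lambdas <- lambda_grid(X, y, alpha, n = nlambda, decades = decades)
    sse <- matrix(0, length(lambdas), 1)
    cnt <- 0
    for (rep in seq_len(reps)) {
      fold <- sample(rep_len(seq_len(k), n))
      for (f in seq_len(k)) {
        tr <- fold != f
        if (sum(tr) < 2 || !any(!tr)) next
        # moderate precision suffices to rank penalties inside the CV
        fits <- suppressWarnings(
          enet_path(X[tr, , drop = FALSE], y[tr], lambdas, alpha,
                    tol = 1e-4, max_iter = 300))
        for (i in seq_along(lambdas)) {
          pr <- predict(fits[[i]], X[!tr, , drop = FALSE])
          sse[i, 1] <- sse[i, 1] + sum((y[!tr] - pr)^2)
        }
      }
      cnt <- cnt + n
    }
    rmse <- sqrt(sse / cnt)
    i <- which.min(rmse)
    if (rmse[i] < best$rmse)
      best <- list(rmse = rmse[i], lambda = lambdas[i], alpha = alpha)
  }
  best
}

#' Nested cross-validated elastic-net prediction
#'
#' Outer leave-one-out cross-validation: for each held-out subject, the
#' penalty pair (lambda, alpha) is chosen on the remaining subjects by
#' repeated inner k-fold cross-validation minimizing RMSE, the model is refit
#' on those subjects, and the held-out subject is predicted. Pooled outer
#' predictions yield RMSE, the relative error (RMSE divided by the observed
#' outcome range), and the Pearson correlation between predicted and observed
#' (with the regression slope test). Residuals are checked for normality
#' (Shapiro-Wilk) and heteroscedasticity (Breusch-Pagan). The RMSE carries a
#' percentile bootstrap CI over outer residuals, and a shuffle test permuting
#' the outcome gives its p value.
#'
#' Predictor standardization (and the skewness check) is refit inside each
#' outer training fold and applied to the held-out subject with training
#' parameters, so no information leaks outward.
#'
#' @param X predictor matrix (raw scale; preprocessing is internal).
#' @param y continuous outcome.
#' @param alphas alpha grid (default `c(0.1, 0.3, 0.5, 0.7, 0.9, 1)`).
#' @param nlambda lambda-grid size (default 50).
#' @param inner_k,inner_reps inner CV folds and repetitions (study-scale
#'   defaults 10 and 10).
#' @param n_boot bootstrap resamples for the RMSE CI (default 1000).
#' @param n_perm shuffle-test permutations (0 skips the test).
#' @param seed integer seed.
#' @return `prediction_report`: rmse (+ CI), relative error, Pearson r,
#'   slope test, residual diagnostics, per-fold coefficient matrix,
#'   always-selected features, shuffle p.
#' @export
nested_cv_enet <- function(X, y, alphas = c(0.1, 0.3, 0.5, 0.7, 0.9, 1),
                           nlambda = 50, inner_k = 10, inner_reps = 10,
                           n_boot = 1000, n_perm = 0, seed = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X)
  stopifnot(n >= 20)
  run_loo <- function(X, y, seed) {
    pred <- numeric(n)
    coefs <- matrix(0, n, ncol(X), dimnames = list(NULL, colnames(X)))
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      Xtr <- preprocess_predictors(X[tr, , drop = FALSE])
      sel <- cv_choose_enet(Xtr, y[tr], alphas, nlambda, k = inner_k,
                            reps = inner_reps,
                            seed = derive_seed(seed, paste0("inner", i)))
      fit <- fit_elastic_net(Xtr, y[tr], sel$lambda, sel$alpha)
      Xte <- apply_preprocess(X[i, , drop = FALSE], Xtr)
      pred[i] <- predict(fit, Xte)
      coefs[i, colnames(Xtr)] <- fit$beta
    }
    list(pred = pred, coefs = coefs)
  }
  main <- run_loo(X, y, seed)
  pred <- main$pred
  resid <- y - pred
  rmse <- sqrt(mean(resid^2))
  rel_error <- rmse / (max(y) - min(y))
  r <- cor(pred, y)
  slope_fit <- lm(scale(y) ~ scale(pred))
  slope <- summary(slope_fit)$coefficients[2, ]
  sw <- shapiro.test(resid)
  bp <- lmtest::bptest(lm(y ~ pred))
  set.seed(derive_seed(seed, "rmse-boot"))
  boot <- vapply(seq_len(n_boot), function(b)
    sqrt(mean(sample(resid^2, n, replace = TRUE))), numeric(1))
  ci <- quantile(boot, c(0.025, 0.975))
  shuffle_p <- NA_real_
  if (n_perm > 0) {
    set.seed(derive_seed(seed, "rmse-shuffle"))
    perm <- vapply(seq_len(n_perm), function(b) {
      yp <- sample(y)
      res <- run_loo(X, yp, derive_seed(seed, paste0("perm", b)))
      sqrt(mean((yp - res$pred)^2))
    }, numeric(1))
    # better-than-chance means smaller RMSE, so count permutations at or below
    shuffle_p <- (1 + sum(perm <= rmse)) / (n_perm + 1)
  }
  stability <- selection_stability(main$coefs)
  structure(list(rmse = rmse, rmse_ci = unname(ci), relative_error = rel_error,
                 pearson_r = r,
                 slope = list(estimate = slope[1], t = slope[3],
                              df = slope_fit$df.residual, p = slope[4]),
                 shapiro_p = sw$p.value, breusch_pagan_p = bp$p.value,
                 predicted = pred, observed = y, coefficients = main$coefs,
                 always_selected = stability, shuffle_p = shuffle_p),
            class = "prediction_report")
}

#' Features selected in every cross-validation fold
#'
#' The strict stability rule: a feature is reported only if its coefficient
#' is nonzero in 100% of the outer fits; mean and SD of those coefficients
#' (standard units) are reported alongside.
#'
#' @param coefs fold x feature coefficient matrix.
#' @return data.frame: feature, mean, sd.
#' @export
selection_stability <- function(coefs) {
  stopifnot(nrow(coefs) >= 2)
  always <- colSums(coefs != 0) == nrow(coefs)
  out <- data.frame(feature = colnames(coefs)[always],
                    mean = colMeans(coefs[, always, drop = FALSE]),
                    sd = apply(coefs[, always, drop = FALSE], 2, sd))
  rownames(out) <- NULL
  out
}
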