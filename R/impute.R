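#' Eligibility filter on ERP data completeness
#'
#' Retains subjects with at least `min_fraction` of their ERP features
#' observed (inclusive boundary). Metadata columns (gender, age, group,
#' outcome, ...) are excluded from the denominator.
#'
#' @param table feature table with the inventory's ERP columns.
#' @param min_fraction minimum observed fraction (default 0.70).
#' @return The filtered table.
#' @export
eligibility_filter <- function(table, min_fraction = 0.70) {
  cols <- intersect(erp_feature_names(), names(table))
  obs_frac <- rowMeans(!is.na(table[, cols, drop = FALSE]))
  table[obs_frac >= min_fraction, , drop = FALSE]
}

#' Expectation-maximization imputation under a multivariate Gaussian
#'
#' Fits a single multivariate normal to the ERP feature block by EM over the
#' missing entries: the E-step replaces missing values by their conditional
#' expectations given the observed entries under the current (mu, Sigma) and
#' accumulates the conditional-covariance correction; the M-step re-estimates
#' (mu, Sigma). Iterates until the relative change in observed-data
#' log-likelihood falls below `tol` or `max_iter` is reached. The imputed
#' table holds the conditional means at convergence. Gender and age are not
#' part of the imputation model.
#'
#' The observed-data log-likelihood is checked to be non-decreasing at every
#' iteration; a materially non-monotone trace signals an implementation bug
#' and raises an error. A singular observed-block covariance is handled by a
#' small ridge (`ridge * trace(Sigma) / p`) with a warning.
#'
#' Estimation is maximum a posteriori under a weakly informative
#' inverse-Wishart prior on the covariance (strength `nu`, mode at the
#' diagonal of the available-case covariance). The unpenalized Gaussian
#' likelihood is unbounded when `n` is not large relative to `p` (the MLE
#' drifts toward a singular covariance), whereas the MAP objective is
#' bounded and the EM ascent on it is provably monotone; the reported
#' trace is this penalized objective. With `nu = 2` and `p = 36` the
#' prior carries the weight of about `p + 3` pseudo-observations.
#'
#' The Gaussian is fitted over the 36 averaged features only: the 18
#' differential features are exact linear combinations of them (the joint
#' distribution over all 54 is degenerate), so they are recomputed from the
#' imputed parents instead, which also keeps the contrast identity exact.
#'
#' @param table feature table (post eligibility filter).
#' @param tol relative objective tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @param ridge ridge fraction for singular observed blocks (default 1e-8).
#' @param nu inverse-Wishart prior strength (default 2).
#' @return List with `table` (imputed) and `model` (mu, Sigma, loglik trace
#'   of the penalized objective, convergence flag, iterations).
#' @export
em_impute <- function(table, tol = 1e-6, max_iter = 500, ridge = 1e-8,
                      nu = 2) {
  cols <- intersect(averaged_feature_names(), names(table))
  X <- as.matrix(table[, cols, drop = FALSE])
  n <- nrow(X); p <- ncol(X)
  miss <- is.na(X)
  if (any(colSums(!miss) < 2))
    stop("every feature must be observed in at least 2 rows")
  if (!any(miss)) {
    mu <- colMeans(X)
    Sigma <- crossprod(sweep(X, 2, mu)) / n
    model <- list(mu = mu, Sigma = Sigma,
                  loglik = em_obs_loglik(X, miss, mu, Sigma, ridge),
                  converged = TRUE, iterations = 1L)
    return(list(table = table, model = model))
  }

  # start from complete-cell moments (available-case means, diagonal spread);
  # the prior scale matrix puts the inverse-Wishart mode at diag(v)
  mu <- colMeans(X, na.rm = TRUE)
  v <- apply(X, 2, var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  Sigma <- diag(v, p)
  Lambda0 <- diag((nu + p + 1) * v, p)
  Xc <- X
  Xc[miss] <- matrix(mu, n, p, byrow = TRUE)[miss]

  patterns <- apply(miss, 1, paste, collapse = "")
  groups_by_pattern <- split(seq_len(n), patterns)
  warned <- FALSE
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step
    C <- matrix(0, p, p) # sum of conditional covariances of missing blocks
    for (rows in groups_by_pattern) {
      m <- miss[rows[1], ]
      if (!any(m)) next
      o <- !m
      if (!any(o)) {
        Xc[rows, ] <- matrix(mu, length(rows), p, byrow = TRUE)
        C[m, m] <- C[m, m] + length(rows) * Sigma[m, m]
        next
      }
      Soo <- Sigma[o, o, drop = FALSE]
      inv <- tryCatch(solve(Soo), error = function(e) NULL)
      if (is.null(inv)) {
        if (!warned) {
          warning("singular observed-block covariance; ridge applied")
          warned <- TRUE
        }
        inv <- solve(Soo + diag(ridge * sum(diag(Sigma)) / p, sum(o)))
      }
      B <- Sigma[m, o, drop = FALSE] %*% inv
      dev <- sweep(X[rows, o, drop = FALSE], 2, mu[o])
      Xc[rows, m] <- matrix(mu[m], length(rows), sum(m), byrow = TRUE) +
        dev %*% t(B)
      cc <- Sigma[m, m, drop = FALSE] - B %*% Sigma[o, m, drop = FALSE]
      C[m, m] <- C[m, m] + length(rows) * cc
    }
    # M-step (MAP): conjugate inverse-Wishart update for the covariance
    mu <- colMeans(Xc)
    Sigma <- (crossprod(sweep(Xc, 2, mu)) + C + Lambda0) / (n + nu + p + 1)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- em_obs_loglik(X, miss, mu, Sigma, ridge) +
      iw_log_prior(Sigma, Lambda0, nu)
    if (length(ll_trace)) {
      prev <- ll_trace[length(ll_trace)]
      if (ll < prev - 1e-6 * abs(prev) - 1e-8)
        stop("EM objective decreased: implementation bug")
    }
    ll_trace <- c(ll_trace, ll)
    if (length(ll_trace) >= 2) {
      prev <- ll_trace[length(ll_trace) - 1]
      if (abs(ll - prev) < tol * (abs(prev) + 1)) { converged <- TRUE; break }
    }
  }
  # one final E-step so the imputed values match the converged parameters
  for (rows in groups_by_pattern) {
    m <- miss[rows[1], ]
    if (!any(m)) next
    o <- !m
    if (!any(o)) { Xc[rows, ] <- matrix(mu, length(rows), p, byrow = TRUE); next }
    Soo <- Sigma[o, o, drop = FALSE]
    inv <- tryCatch(solve(Soo), error = function(e)
      solve(Soo + diag(ridge * sum(diag(Sigma)) / p, sum(o))))
    B <- Sigma[m, o, drop = FALSE] %*% inv
    dev <- sweep(X[rows, o, drop = FALSE], 2, mu[o])
    Xc[rows, m] <- matrix(mu[m], length(rows), sum(m), byrow = TRUE) +
      dev %*% t(B)
  }
  out <- table
  out[, cols] <- Xc
  out <- refresh_contrasts(out)
  list(table = out,
       model = list(mu = mu, Sigma = Sigma, loglik = ll_trace,
                    converged = converged, iterations = length(ll_trace)))
}

# recompute differential columns from parents when both are present
refresh_contrasts <- function(table) {
  if (all(differential_feature_names() %in% names(table)) &&
      all(averaged_feature_names() %in% names(table)))
    table <- apply_contrasts(table)
  table
}

# inverse-Wishart log prior density kernel (constants dropped)
iw_log_prior <- function(Sigma, Lambda0, nu) {
  p <- ncol(Sigma)
  ch <- chol(Sigma)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% Lambda0))
  -0.5 * ((nu + p + 1) * logdet + tr)
}

# observed-data log-likelihood under N(mu, Sigma), summed over missing patterns
em_obs_loglik <- function(X, miss, mu, Sigma, ridge = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  patterns <- apply(miss, 1, paste, collapse = "")
  total <- 0
  for (rows in split(seq_len(n), patterns)) {
    o <- !miss[rows[1], ]
    if (!any(o)) next
    S <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e)
      chol(S + diag(ridge * sum(diag(Sigma)) / p, sum(o))))
    dev <- sweep(X[rows, o, drop = FALSE], 2, mu[o])
    z <- forwardsolve(t(ch), t(dev))
    q <- colSums(z^2)
    total <- total - 0.5 * length(rows) *
      (sum(o) * log(2 * pi) + 2 * sum(log(diag(ch)))) - 0.5 * sum(q)
  }
  total
}

#' Impute new rows under an already-fitted Gaussian model
#'
#' Replaces missing entries by their conditional expectations under fixed
#' `(mu, Sigma)` estimated elsewhere (typically the training split), so no
#' information flows from holdout rows into the imputation model.
#'
#' @param table feature table with `NA`s in the ERP block.
#' @param model the `model` element returned by [em_impute()].
#' @param ridge ridge fraction for singular observed blocks.
#' @return The table with ERP `NA`s filled in.
#' @export
em_apply <- function(table, model, ridge = 1e-8) {
  cols <- intersect(names(model$mu), names(table))
  X <- as.matrix(table[, cols, drop = FALSE])
  miss <- is.na(X)
  if (!any(miss)) return(table)
  mu <- model$mu[cols]
  Sigma <- model$Sigma[cols, cols]
  p <- length(cols)
  for (i in which(rowSums(miss) > 0)) {
    m <- miss[i, ]; o <- !m
    if (!any(o)) { X[i, ] <- mu; next }
    Soo <- Sigma[o, o, drop = FALSE]
    inv <- tryCatch(solve(Soo), error = function(e)
      solve(Soo + diag(ridge * sum(diag(Sigma)) / p, sum(o))))
    X[i, m] <- mu[m] + Sigma[m, o, drop = FALSE] %*% inv %*% (X[i, o] - mu[o])
  }
  table[, cols] <- X
  refresh_contrasts(table)
}

#' Diagnostics for the missing-at-random assumption
#'
#' Compares subjects with complete versus incomplete ERP data on covariates:
#' two-sample Welch t-tests for continuous covariates and chi-square tests
#' for categorical ones, mirroring the usual check that missingness is
#' unrelated to age, gender or outcome.
#'
#' @param table feature table with `NA`s in the ERP block.
#' @param continuous,categorical covariate column names.
#' @return data.frame: covariate, type, statistic, df, p, note.
#' @export
mar_diagnostics <- function(table, continuous = c("age", "outcome"),
                            categorical = "gender") {
  cols <- intersect(erp_feature_names(), names(table))
  incomplete <- rowSums(is.na(table[, cols, drop = FALSE])) > 0
  res <- list()
  for (v in intersect(continuous, names(table))) {
    x <- table[[v]][!incomplete]; y <- table[[v]][incomplete]
    if (sum(is.finite(x)) < 2 || sum(is.finite(y)) < 2) {
      res[[v]] <- data.frame(covariate = v, type = "continuous",
                             statistic = NA, df = NA, p = NA,
                             note = "not-computable")
      next
    }
    tt <- t.test(x, y)
    res[[v]] <- data.frame(covariate = v, type = "continuous",
                           statistic = unname(tt$statistic),
                           df = unname(tt$parameter), p = tt$p.value,
                           note = "")
  }
  for (v in intersect(categorical, names(table))) {
    tab <- table(factor(incomplete, levels = c(FALSE, TRUE)), table[[v]])
    if (ncol(tab) < 2 || any(rowSums(tab) < 2)) {
      res[[v]] <- data.frame(covariate = v, type = "categorical",
                             statistic = NA, df = NA, p = NA,
                             note = "not-computable")
      next
    }
    ct <- suppressWarnings(chisq.test(tab))
    res[[v]] <- data.frame(covariate = v, type = "categorical",
                           statistic = unname(ct$statistic),
                           df = unname(ct$parameter), p = ct$p.value,
                           note = "")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
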