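#' Derive a reproducible sub-seed from a root seed and a stage label
#'
#' Every stochastic stage of the pipeline draws its own seed from the root
#' seed and a fixed character label, so stages are independently reproducible:
#' rerunning one stage with the same root seed gives the same stream no matter
#' which other stages ran before it.
#'
#' @param root_seed integer root seed.
#' @param label character stage label.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root_seed, label) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.character(label))
  h <- abs(as.numeric(root_seed)) %% 2147483647
  for (ch in utf8ToInt(label)) {
    # 32-bit-style multiplicative mixing kept exact in doubles (< 2^53)
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

#' Numerically stable log(exp(a) + exp(b))
#' @param a,b log-scale values.
#' @return log of the summed exponentials.
#' @keywords internal
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(pmin(a, b) - m)))
}

#' Pooled-standard-deviation Cohen's d
#'
#' @param x,y numeric vectors for the two groups.
#' @return Standardized mean difference `(mean(x) - mean(y)) / s_pooled`.
#' @export
cohens_d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (!is.finite(sp2) || sp2 <= 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Sidak family-wise adjustment
#'
#' @param p raw p values.
#' @param m family size (defaults to `length(p)`).
#' @return Adjusted p values `1 - (1 - p)^m`, capped at 1.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(m >= 1)
  if (m == 1) return(p) # exact single-test identity
  pmin(1, -expm1(m * log1p(-p)))
}

#' Standardize matrix columns, optionally with external parameters
#'
#' Centers and scales columns to mean 0 / SD 1; when `center`/`scale` are
#' supplied (e.g. from a training split) they are applied instead, so
#' holdout data can be standardized without leakage. Zero-variance columns
#' get scale 1 and map to a constant 0.
#'
#' @param X numeric matrix.
#' @param center,scale optional externally fitted parameters.
#' @return Standardized matrix with `center` and `scale` attributes.
#' @export
standardize_cols <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  attr(Xs, "center") <- center
  attr(Xs, "scale") <- scale
  Xs
}
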