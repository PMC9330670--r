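#' Hyperparameters for Bayesian hierarchical clustering
#'
#' The model is an independent per-dimension Normal-Gamma conjugate prior
#' (diagonal covariance) with a Dirichlet-process prior over partitions:
#' `alpha` is the DP concentration entering the merge-weight recursion,
#' `(m0, kappa0, a0, b0)` the Normal-Gamma prior on each dimension's mean and
#' precision. The defaults are calibrated to standardized features: they give
#' a prior-predictive variance of `b0 (kappa0 + 1) / (a0 kappa0) = 1` with 4
#' predictive degrees of freedom, so a single standardized observation is
#' typical under the prior. A much weaker mean prior (tiny `kappa0`) makes
#' the predictive so heavy-tailed that early merges become arbitrary and
#' cluster recovery collapses.
#'
#' @param alpha DP concentration (> 0).
#' @param m0 prior mean (default 0).
#' @param kappa0 prior mean strength (> 0, default 1).
#' @param a0 Gamma shape (> 0, default 2).
#' @param b0 Gamma rate (> 0, default 1).
#' @return `bhc_hyperparams` list.
#' @export
bhc_hyperparams <- function(alpha = 1, m0 = 0, kappa0 = 1, a0 = 2, b0 = 1) {
  stopifnot(alpha > 0, kappa0 > 0, a0 > 0, b0 > 0)
  structure(list(alpha = alpha, m0 = m0, kappa0 = kappa0, a0 = a0, b0 = b0),
            class = "bhc_hyperparams")
}

# log marginal likelihood from sufficient statistics: block sizes n (scalar
# or one per row), s (per-dim sums), q (per-dim sums of squares); s and q may
# be matrices with one candidate block per row. Recycling is row-wise.
bhc_log_ml_stats <- function(n, s, q, hyper) {
  s <- rbind(s); q <- rbind(q)
  kn <- hyper$kappa0 + n
  an <- hyper$a0 + n / 2
  xbar <- s / n
  ss <- pmax(q - n * xbar^2, 0)
  bn <- hyper$b0 + 0.5 * ss +
    hyper$kappa0 * n * (xbar - hyper$m0)^2 / (2 * kn)
  per_dim <- lgamma(an) - lgamma(hyper$a0) + hyper$a0 * log(hyper$b0) -
    an * log(bn) + 0.5 * (log(hyper$kappa0) - log(kn)) - (n / 2) * log(2 * pi)
  unname(rowSums(rbind(per_dim)))
}

#' Marginal likelihood of a data block under the conjugate model
#'
#' Product over dimensions of the Normal-Gamma marginal (posterior-to-prior
#' normalizing-constant ratio), returned in log space. For a single point in
#' one dimension this equals the log density of the prior-predictive
#' Student-t (location `m0`, scale^2 `b0 (kappa0 + 1) / (a0 kappa0)`,
#' df `2 a0`).
#'
#' @param X numeric matrix (n x p), one block of subjects.
#' @param hyper a [bhc_hyperparams()].
#' @return Log marginal likelihood (scalar).
#' @export
marginal_likelihood <- function(X, hyper = bhc_hyperparams()) {
  X <- rbind(X)
  if (!all(is.finite(X))) stop("non-finite data")
  bhc_log_ml_stats(nrow(X), colSums(X), colSums(X^2), hyper)
}

#' Build the Bayesian hierarchical clustering tree
#'
#' Greedy bottom-up agglomeration: each subject starts as a leaf; at every
#' step the pair of clusters with the highest posterior merge probability
#' \code{r} is merged, where \code{r} combines the merged-hypothesis marginal
#' likelihood with the Dirichlet-process weight recursion
#' `d_k = alpha Gamma(n_k) + d_i d_j`, `pi_k = alpha Gamma(n_k) / d_k`.
#' All recursion terms are kept in log space. Ties in \code{r} are resolved
#' toward the pair with the smallest combined node index.
#'
#' @param X numeric matrix (n x p), typically standardized averaged features.
#' @param hyper a [bhc_hyperparams()].
#' @return `bhc_tree`: list with `nodes` (one record per node: members,
#'   children, `n`, `log_ml`, `log_pt`, `log_d`, \code{r}) and `root` (index of
#'   the final node). Leaves have \code{r = 1} by convention.
#' @export
build_tree <- function(X, hyper = bhc_hyperparams()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 2)
  if (!all(is.finite(X))) stop("non-finite data")
  p <- ncol(X)
  la <- log(hyper$alpha)

  # node store (grows to 2n - 1)
  nodes <- vector("list", 2 * n - 1)
  S <- matrix(0, 2 * n - 1, p); Q <- matrix(0, 2 * n - 1, p)
  nn <- integer(2 * n - 1)
  log_d <- numeric(2 * n - 1); log_pt <- numeric(2 * n - 1)
  for (i in seq_len(n)) {
    S[i, ] <- X[i, ]; Q[i, ] <- X[i, ]^2; nn[i] <- 1L
    log_d[i] <- la
    log_pt[i] <- bhc_log_ml_stats(1, S[i, ], Q[i, ], hyper)
    nodes[[i]] <- list(members = i, children = NULL, n = 1L,
                       log_ml = log_pt[i], log_pt = log_pt[i],
                       log_d = la, r = 1)
  }

  # candidate statistics for a set of pairs (vectorized over pairs)
  pair_stats <- function(ii, jj) {
    nk <- nn[ii] + nn[jj]
    log_ml <- bhc_log_ml_stats(nk,
                               S[ii, , drop = FALSE] + S[jj, , drop = FALSE],
                               Q[ii, , drop = FALSE] + Q[jj, , drop = FALSE],
                               hyper)
    lg <- la + lgamma(nk)
    ldk <- logaddexp(lg, log_d[ii] + log_d[jj])
    lpi <- lg - ldk
    l1mpi <- log_d[ii] + log_d[jj] - ldk
    lpt <- logaddexp(lpi + log_ml, l1mpi + log_pt[ii] + log_pt[jj])
    list(r = exp(lpi + log_ml - lpt), log_ml = log_ml, log_d = ldk,
         log_pt = lpt)
  }

  active <- seq_len(n)
  ij <- t(utils::combn(active, 2))
  pairs <- cbind(ij, pair_stats(ij[, 1], ij[, 2])$r) # columns: i, j, r

  next_id <- n
  while (length(active) > 1) {
    cand <- which(pairs[, 3] == max(pairs[, 3]))
    if (length(cand) > 1) { # tie: smallest combined node index
      ord <- order(pmin(pairs[cand, 1], pairs[cand, 2]),
                   pmax(pairs[cand, 1], pairs[cand, 2]))
      cand <- cand[ord[1]]
    }
    i <- pairs[cand, 1]; j <- pairs[cand, 2]
    st <- pair_stats(i, j)
    next_id <- next_id + 1L
    k <- next_id
    nn[k] <- nn[i] + nn[j]
    S[k, ] <- S[i, ] + S[j, ]; Q[k, ] <- Q[i, ] + Q[j, ]
    log_d[k] <- st$log_d; log_pt[k] <- st$log_pt
    if (!is.finite(st$log_pt) ||
        st$log_pt < st$log_ml + (la + lgamma(nn[k]) - st$log_d) - 1e-8)
      stop("numerical failure in the tree recursion")
    nodes[[k]] <- list(members = c(nodes[[i]]$members, nodes[[j]]$members),
                       children = c(i, j), n = nn[k], log_ml = st$log_ml,
                       log_pt = st$log_pt, log_d = st$log_d, r = st$r)
    active <- c(setdiff(active, c(i, j)), k)
    drop_rows <- pairs[, 1] %in% c(i, j) | pairs[, 2] %in% c(i, j)
    pairs <- pairs[!drop_rows, , drop = FALSE]
    others <- setdiff(active, k)
    if (length(others)) {
      ps <- pair_stats(rep(k, length(others)), others)
      pairs <- rbind(pairs, cbind(k, others, ps$r))
    }
  }
  structure(list(nodes = nodes[seq_len(next_id)], root = next_id,
                 n = n, hyper = hyper), class = "bhc_tree")
}

#' Cut the tree into the automatic flat partition
#'
#' Traverses from the root: a node with merge posterior \code{r > 0.5} roots a
#' cluster; a node with \code{r <= 0.5} is split and its children examined. The
#' number of clusters is thereby determined by the data.
#'
#' @param tree a `bhc_tree`.
#' @return Integer cluster labels `1..K` in subject order.
#' @export
cut_tree <- function(tree) {
  labels <- integer(tree$n)
  k <- 0L
  visit <- function(id) {
    node <- tree$nodes[[id]]
    if (is.null(node$children) || node$r > 0.5) {
      k <<- k + 1L
      labels[node$members] <<- k
    } else {
      visit(node$children[1])
      visit(node$children[2])
    }
  }
  visit(tree$root)
  labels
}

#' Leave-one-out stability of the clustering
#'
#' For each subject, the tree is rebuilt on the remaining subjects, cut, and
#' the resulting partition compared (adjusted Rand index) with the full-data
#' partition restricted to the same subjects.
#'
#' @param X data matrix.
#' @param hyper a [bhc_hyperparams()].
#' @return List: `mean_ari`, `min_ari`, `ari` (per left-out subject).
#' @export
loo_stability <- function(X, hyper = bhc_hyperparams()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3)
  full <- cut_tree(build_tree(X, hyper))
  ari <- vapply(seq_len(n), function(i) {
    part <- cut_tree(build_tree(X[-i, , drop = FALSE], hyper))
    mclust::adjustedRandIndex(part, full[-i])
  }, numeric(1))
  list(mean_ari = mean(ari), min_ari = min(ari), ari = ari)
}

#' Characterize clusters by feature and outcome differences
#'
#' One-way ANOVA per ERP feature and per outcome variable across clusters,
#' with the Holm-Bonferroni step-down correction applied separately to the
#' ERP family and the outcome family; Tukey HSD pairwise comparisons are
#' reported for variables surviving correction. Clusters of size 1 are
#' excluded with a warning.
#'
#' @param partition integer cluster labels.
#' @param features data.frame of ERP features (the ERP family).
#' @param outcomes optional data.frame of outcome variables (the outcome
#'   family).
#' @param alpha family-wise level for the Tukey follow-up (default 0.05).
#' @return List: `features`, `outcomes` (data.frames with F, df, p, p_holm),
#'   `tukey` (named list of Tukey tables for surviving variables).
#' @export
characterize_clusters <- function(partition, features, outcomes = NULL,
                                  alpha = 0.05) {
  cl <- factor(partition)
  sizes <- table(cl)
  if (any(sizes < 2)) {
    warning("excluding singleton cluster(s): ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    keep <- cl %in% names(sizes)[sizes >= 2]
    features <- features[keep, , drop = FALSE]
    if (!is.null(outcomes)) outcomes <- outcomes[keep, , drop = FALSE]
    cl <- droplevels(cl[keep])
  }
  if (nlevels(cl) < 2) stop("need at least 2 clusters of size >= 2")
  run_family <- function(tab) {
    rows <- lapply(names(tab), function(v) {
      ft <- anova(lm(tab[[v]] ~ cl))
      data.frame(variable = v, F = ft$`F value`[1], df1 = ft$Df[1],
                 df2 = ft$Df[2], p = ft$`Pr(>F)`[1])
    })
    out <- do.call(rbind, rows)
    out$p_holm <- p.adjust(out$p, method = "holm")
    rownames(out) <- NULL
    out
  }
  feat_res <- run_family(features)
  out_res <- if (!is.null(outcomes) && ncol(outcomes)) run_family(outcomes) else NULL
  tukey <- list()
  surv <- feat_res$variable[feat_res$p_holm < alpha]
  if (!is.null(out_res)) surv <- c(surv, out_res$variable[out_res$p_holm < alpha])
  both <- if (is.null(outcomes)) features else cbind(features, outcomes)
  for (v in surv) {
    tk <- TukeyHSD(aov(both[[v]] ~ cl))
    tukey[[v]] <- as.data.frame(tk$cl)
  }
  list(features = feat_res, outcomes = out_res, tukey = tukey)
}

#' Serialize a tree in nested-parenthesis form
#'
#' Leaves print their subject index; internal nodes print their two children
#' and the merge posterior, e.g. `"(1,(2,3):r=0.91):r=0.12"`.
#'
#' @param tree a `bhc_tree`.
#' @return Character scalar.
#' @export
format_tree <- function(tree) {
  fmt <- function(id) {
    node <- tree$nodes[[id]]
    if (is.null(node$children)) return(as.character(node$members))
    sprintf("(%s,%s):r=%.3f", fmt(node$children[1]), fmt(node$children[2]),
            node$r)
  }
  fmt(tree$root)
}
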