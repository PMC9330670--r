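#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen positive scores above a randomly chosen
#' negative, ties counting one half.
#'
#' @param scores numeric decision values, higher meaning more positive.
#' @param labels binary labels; `pos_label` marks the positive class.
#' @param pos_label value of `labels` treated as positive.
#' @return AUC as a fraction in `[0, 1]`.
#' @export
auc <- function(scores, labels, pos_label = 1) {
  pos <- labels == pos_label
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified train/holdout split
#'
#' Positives and negatives are split independently: per class,
#' `round(train_fraction * n_class)` subjects go to the main sample and the
#' remainder to the holdout, so the class ratios of the two splits differ by
#' at most one subject per class. Deterministic for a given seed.
#'
#' @param labels binary outcome vector.
#' @param train_fraction fraction assigned to the main sample (default 0.70).
#' @param seed integer seed.
#' @param pos_label positive-class value.
#' @return List with integer index vectors `main` and `holdout`.
#' @export
stratified_split <- function(labels, train_fraction = 0.70, seed = 1,
                             pos_label = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be strictly inside (0, 1)")
  idx_pos <- which(labels == pos_label)
  idx_neg <- which(labels != pos_label)
  if (length(idx_pos) < 2 || length(idx_neg) < 2)
    stop("each class needs at least 2 members")
  set.seed(seed)
  take <- function(idx) {
    k <- round(train_fraction * length(idx))
    sample(idx)[seq_len(k)]
  }
  main <- sort(c(take(idx_pos), take(idx_neg)))
  list(main = main, holdout = setdiff(seq_along(labels), main))
}

#' Fit a soft-margin linear SVM
#'
#' Trains the linear support-vector machine (hinge loss, fixed regularization
#' `C`) by dual coordinate descent; the bias is handled through an augmented
#' constant feature. Decision values are oriented so that larger means more
#' likely positive.
#'
#' @param X numeric matrix (standardize beforehand; see [cv_auc()]).
#' @param y binary labels.
#' @param C soft-margin cost (default 1; no internal tuning).
#' @param pos_label positive-class value.
#' @param tol,max_epochs solver controls; the default tolerance 0.1 on the
#'   projected-gradient range is the usual dual-solver default and ample for
#'   decision-value ranking.
#' @param seed integer seed for the solver's coordinate permutations.
#' @return `linear_svm` object with `w`, `b` and a `predict` method.
#' @export
linear_svm <- function(X, y, C = 1, pos_label = 1, tol = 0.1,
                       max_epochs = 1000, seed = 1) {
  X <- as.matrix(X)
  yy <- ifelse(y == pos_label, 1, -1)
  if (length(unique(yy)) < 2) stop("training data contain one class only")
  fit <- svm_dcd(X, yy, C, 1.0, tol, as.integer(max_epochs), as.integer(seed))
  structure(list(w = drop(fit$w), b = fit$b, C = C, pos_label = pos_label,
                 converged = fit$converged, epochs = fit$epochs),
            class = "linear_svm")
}

#' @rdname linear_svm
#' @param object a `linear_svm` fit.
#' @param newdata matrix of observations to score.
#' @param ... unused.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$w) + object$b
}

# stratified k-fold assignment: within each class, shuffled round-robin
stratified_folds <- function(y, k, pos_label = 1) {
  fold <- integer(length(y))
  for (cls in list(y == pos_label, y != pos_label)) {
    idx <- sample(which(cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated AUC of the linear SVM on a feature subset
#'
#' Stratified k-fold cross-validation: per fold the masked features are
#' standardized with training-fold parameters only, a linear SVM is trained,
#' and the held-out decision values are pooled across folds into a single
#' AUC. This is the fitness function of the genetic feature search. If a
#' training fold ends up single-class the folds are re-randomized (up to 10
#' attempts).
#'
#' @param X feature matrix (subjects x inventory).
#' @param y binary labels.
#' @param mask logical/0-1 vector over columns of `X`; default all.
#' @param k folds (default 10).
#' @param seed fold-assignment seed.
#' @param C SVM cost.
#' @param pos_label positive-class value.
#' @return Pooled cross-validated AUC (fraction).
#' @export
cv_auc <- function(X, y, mask = NULL, k = 10, seed = 1, C = 1, pos_label = 1) {
  X <- as.matrix(X)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (!any(mask)) stop("empty feature mask")
    X <- X[, mask, drop = FALSE]
  }
  n <- nrow(X)
  if (n < k) stop("need n >= k")
  set.seed(seed)
  for (attempt in 1:10) {
    fold <- stratified_folds(y, k, pos_label)
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold != f])) == 2, logical(1)))
    if (ok) break
    if (attempt == 10) stop("could not build two-class training folds")
  }
  scores <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (!any(!tr)) next
    Xtr <- standardize_cols(X[tr, , drop = FALSE])
    fit <- linear_svm(Xtr, y[tr], C = C, pos_label = pos_label,
                      seed = seed + f)
    Xte <- standardize_cols(X[!tr, , drop = FALSE],
                            center = attr(Xtr, "center"),
                            scale = attr(Xtr, "scale"))
    scores[!tr] <- predict(fit, Xte)
  }
  auc(scores, y, pos_label)
}

#' Train on the main sample and evaluate on the holdout
#'
#' Standardization parameters and the classification threshold come from the
#' main sample only: the threshold maximizes Youden's J (sensitivity +
#' specificity - 1) over the main-sample decision values. Holdout metrics
#' (AUC, sensitivity, specificity, accuracy, PPV, NPV) carry percentile
#' bootstrap confidence intervals over holdout resamples.
#'
#' @param X_main,y_main main (training) sample.
#' @param X_hold,y_hold holdout sample.
#' @param mask feature mask (logical over columns).
#' @param C SVM cost.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @param pos_label positive-class value.
#' @return `classifier_report`: data.frame `metrics` (metric, value, lo, hi)
#'   plus the holdout scores and threshold.
#' @export
evaluate_holdout <- function(X_main, y_main, X_hold, y_hold, mask = NULL,
                             C = 1, n_boot = 10000, seed = 1, conf = 0.95,
                             pos_label = 1) {
  X_main <- as.matrix(X_main); X_hold <- as.matrix(X_hold)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (!any(mask)) stop("empty feature mask")
    X_main <- X_main[, mask, drop = FALSE]
    X_hold <- X_hold[, mask, drop = FALSE]
  }
  Xtr <- standardize_cols(X_main)
  fit <- linear_svm(Xtr, y_main, C = C, pos_label = pos_label, seed = seed)
  s_main <- predict(fit, Xtr)
  thr <- youden_threshold(s_main, y_main, pos_label)
  Xte <- standardize_cols(X_hold, center = attr(Xtr, "center"),
                          scale = attr(Xtr, "scale"))
  s_hold <- predict(fit, Xte)

  point <- holdout_metrics(s_hold, y_hold, thr, pos_label)
  set.seed(seed)
  nh <- length(y_hold)
  boot <- matrix(NA_real_, n_boot, length(point))
  for (b in seq_len(n_boot)) {
    ii <- sample.int(nh, nh, replace = TRUE)
    if (length(unique(y_hold[ii])) < 2) next # resample lacks a class
    boot[b, ] <- holdout_metrics(s_hold[ii], y_hold[ii], thr, pos_label)
  }
  a <- (1 - conf) / 2
  ci <- apply(boot, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE)
  metrics <- data.frame(metric = names(point), value = unname(point),
                        lo = ci[1, ], hi = ci[2, ])
  rownames(metrics) <- NULL
  structure(list(metrics = metrics, scores = s_hold, labels = y_hold,
                 threshold = thr, fit = fit),
            class = "classifier_report")
}

youden_threshold <- function(scores, labels, pos_label = 1) {
  cand <- sort(unique(scores))
  cand <- c(cand[1] - 1, (cand[-1] + cand[-length(cand)]) / 2, cand[length(cand)] + 1)
  j <- vapply(cand, function(t) {
    pred <- scores > t
    sens <- mean(pred[labels == pos_label])
    spec <- mean(!pred[labels != pos_label])
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

holdout_metrics <- function(scores, labels, threshold, pos_label = 1) {
  pred <- scores > threshold
  pos <- labels == pos_label
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  c(auc = auc(scores, labels, pos_label),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(labels),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Permutation (shuffle) test of a performance statistic against chance
#'
#' Permutes the outcome labels `n_perm` times, re-running the full evaluation
#' per permutation, and returns `p = (1 + #{stat_perm >= stat_obs}) /
#' (n_perm + 1)`.
#'
#' @param stat_fn function `(X, y) -> numeric` running the whole pipeline
#'   under test (e.g. a cross-validated AUC).
#' @param X feature matrix passed through to `stat_fn`.
#' @param y outcome labels to permute.
#' @param n_perm permutations (>= 100; the study-scale default is 10000).
#' @param seed integer seed.
#' @return List: `p`, `observed`, `permuted` (vector of length `n_perm`).
#' @export
shuffle_test <- function(stat_fn, X, y, n_perm = 10000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  observed <- stat_fn(X, y)
  set.seed(seed)
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    val <- NA_real_
    for (try in 1:3) {
      yp <- sample(y)
      val <- tryCatch(stat_fn(X, yp), error = function(e) NA_real_)
      if (is.finite(val)) break
    }
    perm[b] <- val
  }
  list(p = (1 + sum(perm >= observed, na.rm = TRUE)) / (n_perm + 1),
       observed = observed, permuted = perm)
}

#' Paired permutation comparison of two classifiers
#'
#' Both classifiers must be scored on the same holdout subjects. Per
#' permutation the two score vectors are randomly swapped within subjects and
#' the absolute AUC difference recomputed; two-sided p value by the usual
#' `(1 + #{|delta_perm| >= |delta_obs|}) / (n_perm + 1)` rule.
#'
#' @param scores_a,scores_b decision values of the two classifiers.
#' @param labels shared holdout labels.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param pos_label positive-class value.
#' @return List: `p`, `delta_obs`.
#' @export
compare_classifiers <- function(scores_a, scores_b, labels, n_perm = 10000,
                                seed = 1, pos_label = 1) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("score vectors and labels must cover the same subjects")
  delta_obs <- auc(scores_a, labels, pos_label) - auc(scores_b, labels, pos_label)
  set.seed(seed)
  n <- length(labels)
  count <- 0
  for (b in seq_len(n_perm)) {
    swap <- runif(n) < 0.5
    a2 <- ifelse(swap, scores_b, scores_a)
    b2 <- ifelse(swap, scores_a, scores_b)
    d <- auc(a2, labels, pos_label) - auc(b2, labels, pos_label)
    if (abs(d) >= abs(delta_obs) - 1e-12) count <- count + 1
  }
  list(p = (1 + count) / (n_perm + 1), delta_obs = delta_obs)
}
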