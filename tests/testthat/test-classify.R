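brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels != 1]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

test_that("AUC matches exhaustive pair enumeration, including ties", {
  expect_equal(auc(c(3, 2, 1, 2), c(1, 1, 0, 0)), 0.875)
  expect_equal(auc(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(2, 6), rep(c(1, 0), 3)), 0.5)
  set.seed(2)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- sample(1:5, n, replace = TRUE) # coarse grid to force ties
    expect_equal(auc(scores, labels), brute_force_auc(scores, labels))
  }
  expect_error(auc(1:4, rep(1, 4)), "both classes")
})

test_that("stratified split reproduces the cohort's published sizes", {
  labels <- rep(c(1, 0), c(33, 111))
  s <- stratified_split(labels, 0.70, seed = 1)
  expect_identical(length(s$main), 101L)
  expect_identical(length(s$holdout), 43L)
  expect_identical(sum(labels[s$main]), 23)
  expect_identical(sum(labels[s$holdout]), 10)
  # determinism and partition property
  s2 <- stratified_split(labels, 0.70, seed = 1)
  expect_identical(s, s2)
  expect_identical(sort(c(s$main, s$holdout)), seq_along(labels))
  expect_error(stratified_split(labels, 1.0), "train_fraction")
  expect_error(stratified_split(rep(c(1, 0), c(1, 50)), 0.7), "class")
})

test_that("class ratios of the two splits differ by at most one per class", {
  set.seed(4)
  for (i in 1:10) {
    npos <- sample(10:60, 1); nneg <- sample(30:120, 1)
    labels <- sample(rep(c(1, 0), c(npos, nneg)))
    s <- stratified_split(labels, 0.70, seed = i)
    expect_lte(abs(sum(labels[s$main]) - round(0.7 * npos)), 1)
    expect_lte(abs(sum(labels[s$holdout] == 0) - (nneg - round(0.7 * nneg))), 1)
  }
})

test_that("the dual solver agrees with a reference SVM implementation", {
  set.seed(1)
  n <- 150
  X <- scale(matrix(rnorm(n * 6), n))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n) > 0)
  fit <- linear_svm(X, y, C = 1, tol = 1e-3)
  ref <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
  dv <- attr(predict(ref, X, decision.values = TRUE), "decision.values")
  if (colnames(dv)[1] == "0/1") dv <- -dv
  expect_gt(cor(predict(fit, X), drop(dv)), 0.999)
  expect_error(linear_svm(X, rep(1, n)), "one class")
})

test_that("cross-validated AUC separates signal from chance", {
  tb <- iid_class_table(n = 200, p = 5, planted = 1, d = 3, seed = 6)
  expect_gt(cv_auc(tb$X, tb$y, k = 10, seed = 1), 0.95)

  # null calibration over repeated draws
  aucs <- vapply(1:200, function(s) {
    tb0 <- iid_class_table(n = 60, p = 4, seed = 1000 + s)
    cv_auc(tb0$X, tb0$y, k = 10, seed = s)
  }, numeric(1))
  expect_gt(mean(aucs), 0.45); expect_lt(mean(aucs), 0.55)

  # duplication invariance (within CV tolerance)
  tb2 <- iid_class_table(n = 100, p = 4, planted = 1, d = 1.5, seed = 7)
  a1 <- cv_auc(tb2$X, tb2$y, k = 10, seed = 3)
  a2 <- cv_auc(rbind(tb2$X, tb2$X), c(tb2$y, tb2$y), k = 10, seed = 3)
  expect_lt(abs(a1 - a2), 0.06)

  expect_error(cv_auc(tb2$X, tb2$y, mask = rep(FALSE, 4)), "empty")
})

test_that("holdout evaluation produces coherent ROC metrics and CIs", {
  tb <- iid_class_table(n = 120, p = 4, planted = 1:2, d = 4, seed = 9)
  rep <- evaluate_holdout(tb$X[1:80, ], tb$y[1:80], tb$X[81:120, ],
                          tb$y[81:120], n_boot = 300, seed = 1)
  m <- rep$metrics
  expect_true(all(m$value >= m$lo - 1e-12 & m$value <= m$hi + 1e-12))
  expect_equal(m$value[m$metric == "auc"], 1) # d = 4: complete separation
  expect_equal(m$value[m$metric == "sensitivity"], 1)
  expect_equal(m$lo[m$metric == "auc"], 1) # degenerate CI at perfection

  # confusion arithmetic on constructed predictions
  scores <- c(rep(1, 25), rep(-1, 9), rep(-1, 7), rep(1, 2))
  labels <- rep(c(1, 0), c(34, 9))
  met <- faceerp:::holdout_metrics(scores, labels, 0)
  expect_equal(met[["sensitivity"]], 25 / 34)
  expect_equal(met[["specificity"]], 7 / 9)
  expect_equal(met[["ppv"]], 25 / 27)
  expect_equal(met[["npv"]], 7 / 16)
  expect_equal(met[["accuracy"]], 32 / 43)
})

test_that("shuffle test follows the permutation p-value formula", {
  # observed beats every permutation: p at the formula floor
  tb <- iid_class_table(n = 60, p = 3, planted = 1, d = 5, seed = 11)
  st <- shuffle_test(function(X, y) cv_auc(X, y, k = 5, seed = 1),
                     tb$X, tb$y, n_perm = 100, seed = 2)
  expect_equal(st$p, 1 / 101)
  expect_identical(st$p, (1 + sum(st$permuted >= st$observed)) / 101)

  # constructed stat stream: 30 of 100 permutations at or above the observed
  vals <- local({
    i <- 0
    stream <- c(0.7, rep(0.8, 30), rep(0.1, 70))
    function(X, y) { i <<- i + 1; stream[i] }
  })
  st2 <- shuffle_test(vals, NULL, 1:10, n_perm = 100, seed = 1)
  expect_equal(st2$p, 31 / 101)
  expect_error(shuffle_test(function(X, y) 1, NULL, 1:10, n_perm = 10), "n_perm")
})

test_that("paired classifier comparison is exact under identity and power", {
  set.seed(13)
  labels <- rep(c(1, 0), each = 30)
  s <- rnorm(60)
  expect_equal(compare_classifiers(s, s, labels, n_perm = 200, seed = 1)$p, 1)
  good <- labels + rnorm(60, 0, 0.1)
  bad <- rnorm(60)
  cmp <- compare_classifiers(good, bad, labels, n_perm = 500, seed = 1)
  expect_lt(cmp$p, 0.01)
  expect_error(compare_classifiers(s[-1], s, labels), "same subjects")
})
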