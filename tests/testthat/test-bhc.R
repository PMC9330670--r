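test_that("a singleton's marginal likelihood is the prior-predictive t density", {
  h <- bhc_hyperparams(kappa0 = 0.01, a0 = 1, b0 = 1) # deliberately diffuse
  for (x in c(-2.3, 0, 0.7, 4)) {
    scale2 <- h$b0 * (h$kappa0 + 1) / (h$a0 * h$kappa0)
    ref <- dt((x - h$m0) / sqrt(scale2), df = 2 * h$a0, log = TRUE) -
      0.5 * log(scale2)
    expect_equal(marginal_likelihood(matrix(x, 1, 1), h), ref)
  }
})

test_that("the block marginal matches semi-analytic integration in 1-D", {
  h <- bhc_hyperparams()
  x <- c(0.4, -1.1, 0.9)
  # integrate the Normal-Gamma mixture over tau; the mean integrates in
  # closed form inside (Gaussian-Gaussian convolution)
  joint_given_tau <- function(tau) {
    n <- length(x)
    kn <- h$kappa0 + n
    xbar <- mean(x)
    ss <- sum((x - xbar)^2)
    quad <- ss + h$kappa0 * n * (xbar - h$m0)^2 / kn
    (tau / (2 * pi))^(n / 2) * sqrt(h$kappa0 / kn) * exp(-tau * quad / 2) *
      h$b0^h$a0 / gamma(h$a0) * tau^(h$a0 - 1) * exp(-h$b0 * tau)
  }
  ref <- integrate(Vectorize(joint_given_tau), 0, Inf, rel.tol = 1e-10)$value
  expect_equal(marginal_likelihood(matrix(x, 3, 1), h), log(ref),
               tolerance = 1e-7)
})

test_that("the marginal is exchangeable and penalizes merging far points", {
  h <- bhc_hyperparams()
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(marginal_likelihood(X, h),
               marginal_likelihood(X[c(3, 1, 4, 2), ], h))
  far <- matrix(c(-4, 4), 2, 1)
  expect_lt(marginal_likelihood(far, h),
            marginal_likelihood(far[1, , drop = FALSE], h) +
              marginal_likelihood(far[2, , drop = FALSE], h))
  expect_error(marginal_likelihood(matrix(c(1, NA), 2, 1), h), "non-finite")
})

test_that("the two-leaf recursion obeys the closed-form DP algebra", {
  for (a0 in c(0.5, 1, 2)) {
    h <- bhc_hyperparams(alpha = a0)
    tr <- build_tree(matrix(c(0.1, 0.12), 2, 1), h)
    root <- tr$nodes[[tr$root]]
    expect_equal(root$log_d, log(a0 + a0^2))
    lpi <- log(a0) + lgamma(2) - root$log_d
    expect_equal(exp(lpi), 1 / (1 + a0))
  }
})

test_that("greedy construction matches the exhaustive oracle for small n", {
  h <- bhc_hyperparams()
  set.seed(9)
  for (i in 1:6) {
    n <- sample(3:6, 1)
    X <- matrix(rnorm(n * 2), n)
    if (i %% 2 == 0) X[seq_len(floor(n / 2)), ] <- X[seq_len(floor(n / 2)), ] + 3
    tree <- build_tree(X, h)
    expect_identical(tree_merges(tree), oracle_bhc_merges(X, h))
  }
})

test_that("every internal node satisfies the mixture bound", {
  set.seed(10)
  X <- rbind(matrix(rnorm(30), 15, 2), matrix(rnorm(30, 3), 15, 2))
  tree <- build_tree(X, bhc_hyperparams())
  for (k in (tree$n + 1):length(tree$nodes)) {
    nd <- tree$nodes[[k]]
    lpi <- log(tree$hyper$alpha) + lgamma(nd$n) - nd$log_d
    ch <- nd$children
    expect_gte(nd$log_pt, lpi + nd$log_ml - 1e-8)
    expect_gte(nd$log_pt, (tree$nodes[[ch[1]]]$log_d + tree$nodes[[ch[2]]]$log_d -
                             nd$log_d) +
                 tree$nodes[[ch[1]]]$log_pt + tree$nodes[[ch[2]]]$log_pt - 1e-8)
    expect_true(nd$r >= 0 && nd$r <= 1)
  }
})

test_that("the automatic cut finds planted structure and respects ordering", {
  h <- bhc_hyperparams()
  # tight single blob: one cluster
  set.seed(11)
  X1 <- matrix(rnorm(40, 0, 0.2), 20, 2)
  expect_identical(max(cut_tree(build_tree(scale(X1), h))), 1L)

  # two well-separated blobs: exact recovery
  X2 <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60, 6), 30, 2))
  part <- cut_tree(build_tree(X2, h))
  expect_identical(max(part), 2L)
  expect_equal(mclust::adjustedRandIndex(part, rep(1:2, each = 30)), 1)

  # subject order invariance
  perm <- sample(60)
  part_p <- cut_tree(build_tree(X2[perm, ], h))
  expect_equal(mclust::adjustedRandIndex(part_p, part[perm]), 1)
})

test_that("leave-one-out stability is perfect for separated clusters", {
  set.seed(12)
  X <- rbind(matrix(rnorm(24, 0, 0.5), 12, 2), matrix(rnorm(24, 20, 0.5), 12, 2))
  st <- loo_stability(X, bhc_hyperparams())
  expect_equal(st$mean_ari, 1)
  expect_equal(st$min_ari, 1)
  expect_length(st$ari, 24)
})

test_that("cluster characterization applies Holm per family and Tukey follow-ups", {
  set.seed(13)
  n <- 60
  cl <- rep(1:3, each = 20)
  feats <- data.frame(sig = rnorm(n) + cl, null1 = rnorm(n), null2 = rnorm(n))
  outs <- data.frame(score = rnorm(n))
  rep <- characterize_clusters(cl, feats, outs)
  expect_identical(rep$features$p_holm,
                   p.adjust(rep$features$p, method = "holm"))
  expect_identical(rep$outcomes$p_holm, rep$outcomes$p) # m = 1 identity
  expect_lt(rep$features$p_holm[rep$features$variable == "sig"], 0.05)
  expect_true("sig" %in% names(rep$tukey))
  expect_identical(nrow(rep$tukey$sig), 3L) # 3 pairwise contrasts

  # singleton clusters are excluded with a warning
  cl2 <- c(rep(1, 29), rep(2, 29), 3, 4)
  expect_warning(characterize_clusters(cl2, feats, outs), "singleton")
})

test_that("the tree serialization carries merge posteriors", {
  X <- matrix(c(0, 0.1, 5), 3, 1)
  txt <- format_tree(build_tree(X, bhc_hyperparams()))
  expect_match(txt, "^\\(.*\\):r=")
  expect_match(txt, "\\(1,2\\)") # the close pair merges first
})
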