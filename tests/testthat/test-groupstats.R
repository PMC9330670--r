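test_that("degenerate all-equal input is NaN-guarded", {
  vals <- matrix(1, 30, 2)
  g <- rep(c("a", "b", "c"), each = 10)
  res <- splitplot_anova(vals, g)
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))
})

test_that("interaction F equals the one-way F on difference scores", {
  for (seed in 1:5) {
    set.seed(seed)
    ns <- sample(8:20, 3)
    g <- rep(c("a", "b", "c"), ns)
    vals <- cbind(rnorm(sum(ns), rep(c(0, .3, .6), ns)), rnorm(sum(ns)))
    res <- splitplot_anova(vals, g)
    oracle <- oneway.test((vals[, 1] - vals[, 2]) ~ g, var.equal = TRUE)
    expect_equal(res$F[res$effect == "condition:group"],
                 unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(res$p[res$effect == "condition:group"],
                 oracle$p.value, tolerance = 1e-10)
  }
})

test_that("all three strata match the classical repeated-measures fit", {
  set.seed(7)
  ns <- c(12, 15, 18); N <- sum(ns)
  g <- factor(rep(c("a", "b", "c"), ns))
  vals <- cbind(rnorm(N, rep(c(0, .5, 1), ns)), rnorm(N))
  res <- splitplot_anova(vals, g)
  long <- data.frame(y = c(vals[, 1], vals[, 2]),
                     cond = factor(rep(c("c1", "c2"), each = N)),
                     subj = factor(rep(seq_len(N), 2)), g = rep(g, 2))
  av <- summary(aov(y ~ cond * g + Error(subj), data = long))
  between <- av[["Error: subj"]][[1]]
  within <- av[["Error: Within"]][[1]]
  rownames(between) <- trimws(rownames(between))
  rownames(within) <- trimws(rownames(within))
  expect_equal(res$F[res$effect == "group"], between["g", "F value"],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$F[res$effect == "condition"], within["cond", "F value"],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$F[res$effect == "condition:group"],
               within["cond:g", "F value"], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("null simulation keeps the interaction test calibrated", {
  set.seed(101)
  reps <- 1000
  p <- vapply(seq_len(reps), function(i) {
    g <- rep(c("a", "b", "c"), each = 12)
    vals <- cbind(rnorm(36), rnorm(36))
    res <- splitplot_anova(vals, g)
    res$p[res$effect == "condition:group"]
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.037); expect_lte(rate, 0.064)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("subjects missing a condition value are dropped with a message", {
  vals <- cbind(rnorm(30), rnorm(30)); vals[5, 2] <- NA
  g <- rep(c("a", "b", "c"), each = 10)
  expect_message(res <- splitplot_anova(vals, g), "dropped")
  expect_equal(res$df2[res$effect == "group"], 26)
})

test_that("covariate adjustment respects orthogonality and degeneracy", {
  set.seed(15)
  n <- 90
  g <- rep(c("a", "b", "c"), each = 30)
  vals <- cbind(rnorm(n, rep(c(0, .4, .8), each = 30)), rnorm(n))
  raw <- splitplot_anova(vals, g)

  # independent covariate: F within tolerance of unadjusted
  cov_orth <- data.frame(age = rnorm(n))
  adj <- ancova_adjust(vals, g, cov_orth)
  expect_equal(adj$F[adj$effect == "condition:group"],
               raw$F[raw$effect == "condition:group"], tolerance = 0.2)

  # constant covariate dropped with a warning
  expect_warning(ancova_adjust(vals, g, data.frame(k = rep(1, n))), "constant")

  # fully mediating covariate removes a planted interaction: the condition
  # difference tracks a covariate whose mean differs by group
  set.seed(17)
  med <- rnorm(n) + rep(c(0, 1, 2), each = 30)
  vals2 <- cbind(0.1 * rnorm(n) + med, rnorm(n) * 0.1)
  covm <- data.frame(m = med)
  raw2 <- splitplot_anova(vals2, g)
  adj2 <- ancova_adjust(vals2, g, covm)
  expect_lt(raw2$p[raw2$effect == "condition:group"], 0.05)
  expect_gt(adj2$p[adj2$effect == "condition:group"], 0.05)
})

test_that("post-hoc effect sizes and Sidak adjustment behave", {
  set.seed(20)
  x <- rnorm(2000, 1, 1); y <- rnorm(2000, 0, 1)
  res <- posthoc_d(x, y)
  expect_equal(res$d, 1, tolerance = 0.08)

  same <- rnorm(50)
  res2 <- posthoc_d(same, same)
  expect_equal(res2$d, 0)
  expect_gt(res2$p, 0.99)

  res3 <- posthoc_d(x, y, m = 1)
  expect_identical(res3$p, res3$p_sidak) # single-test identity

  p <- runif(20)
  expect_true(all(sidak_adjust(p, 3) >= p))
  expect_true(all(sidak_adjust(p, 3) <= 1))

  tab <- posthoc_table(c(x[1:30], y[1:30], rnorm(30)),
                       rep(c("g1", "g2", "g3"), each = 30))
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$p_sidak >= tab$p))
})

test_that("estimated d converges to the planted value", {
  cfg <- generator_config(
    n_per_group = c("TL" = 2000, "EL-noASD" = 2000, "EL-ASD" = 2000),
    effects = list(effect_spec("P400_amp_SD", "EL-ASD", 0.5)),
    outcome_beta = numeric(0), miss_rate = 0, seed = 31)
  f <- generate_feature_table(cfg)$features
  d <- cohens_d(f$P400_amp_SD[f$group == "EL-ASD"],
                f$P400_amp_SD[f$group == "TL"])
  expect_lt(abs(d - 0.5), 0.1) # ~3 Monte-Carlo SEs at n = 2000/group
})
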