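test_that("feature inventory has the documented size and order", {
  inv <- build_feature_inventory()
  expect_length(inv, 56)
  expect_false(any(grepl("FvN|DvA|TvA", inv[1:36])))
  expect_true(all(grepl("FvN|DvA|TvA", inv[37:54])))
  expect_identical(inv[55:56], c("gender", "age"))
  expect_identical(setdiff(inv, c("gender", "age")), erp_feature_names())
})

test_that("identical config and seed give a bit-identical cohort", {
  cfg <- generator_config(n_per_group = c("TL" = 10, "EL-noASD" = 10, "EL-ASD" = 10),
                          seed = 42)
  expect_identical(generate_feature_table(cfg), generate_feature_table(cfg))
})

test_that("null configuration plants no group differences", {
  cfg <- generator_config(n_per_group = c("TL" = 200, "EL-noASD" = 200, "EL-ASD" = 200),
                          effects = list(), outcome_beta = numeric(0),
                          miss_rate = 0, seed = 3)
  f <- generate_feature_table(cfg)$features
  for (col in c("P1_lat_TvA", "N290_lat_FvN", "P400_amp_SD")) {
    for (g in c("TL", "EL-noASD", "EL-ASD")) {
      x <- f[[col]][f$group == g]
      expect_lt(abs(mean(x)) / (sd(x) / sqrt(length(x))), 3.5)
    }
  }
})

test_that("a planted contrast effect is recovered at Monte Carlo scale", {
  cfg <- generator_config(
    n_per_group = c("TL" = 2000, "EL-noASD" = 2000, "EL-ASD" = 2000),
    effects = list(effect_spec("P1_lat_TvA", "EL-ASD", 0.74)),
    outcome_beta = numeric(0), miss_rate = 0, seed = 11)
  f <- generate_feature_table(cfg)$features
  x <- f$P1_lat_TvA[f$group == "EL-ASD"]
  d_within <- mean(x) / sd(x)
  expect_gt(d_within, 0.67)
  expect_lt(d_within, 0.81)
})

test_that("differential features equal parent differences exactly", {
  co <- small_cohort(seed = 9)
  f <- co$features
  cp <- faceerp:::contrast_parents()
  for (nm in differential_feature_names()) {
    pf <- faceerp:::parse_feature_name(nm)
    par <- cp[[pf$suffix]]
    a <- paste(pf$component, pf$measure, par[1], sep = "_")
    b <- paste(pf$component, pf$measure, par[2], sep = "_")
    expect_identical(f[[nm]], f[[a]] - f[[b]])
  }
})

test_that("zero outcome coefficients leave features uncorrelated with outcome", {
  cfg <- generator_config(n_per_group = c("TL" = 0, "EL-noASD" = 300, "EL-ASD" = 100),
                          effects = list(), outcome_beta = numeric(0),
                          miss_rate = 0, seed = 5)
  f <- generate_feature_table(cfg)$features
  rs <- vapply(averaged_feature_names(),
               function(nm) cor(f[[nm]], f$outcome), numeric(1))
  expect_lt(max(abs(rs)), 4 / sqrt(nrow(f)))
})

test_that("missingness injection matches rate, mechanism and bookkeeping", {
  co <- small_cohort(100, 100, 100, seed = 21)
  expect_identical(inject_missingness(co, 0), co)

  co2 <- inject_missingness(co, 0.1, "MCAR")
  M <- as.matrix(co2$features[, averaged_feature_names()])
  frac <- mean(is.na(M)) # 300 x 36 cells
  expect_gt(frac, 0.08); expect_lt(frac, 0.12)
  expect_identical(co2$truth$missingness, "MCAR")
  # masked parents propagate into contrasts
  expect_true(all(is.na(co2$features$P1_amp_FvN[is.na(co2$features$P1_amp_F)])))

  expect_error(inject_missingness(co, 1), "miss_rate")

  # MAR-on-age: masking depends on age, not on feature values given age
  co3 <- inject_missingness(co, 0.3, "MAR-age")
  nmiss <- rowSums(is.na(co3$features[, averaged_feature_names()]))
  fit <- glm(cbind(nmiss, 36 - nmiss) ~ age, data = co3$features,
             family = binomial)
  expect_lt(summary(fit)$coefficients["age", "Pr(>|z|)"], 1e-4)
})

test_that("planted clusters are recorded and recoverable", {
  cs1 <- make_cluster_spec(1, separation = 0)
  cfg1 <- generator_config(n_per_group = c("TL" = 0, "EL-noASD" = 10, "EL-ASD" = 5),
                           cluster_spec = cs1, miss_rate = 0, seed = 2)
  expect_true(all(plant_clusters(cfg1)$truth$cluster == 1))

  cs2 <- make_cluster_spec(2, separation = 6)
  cfg2 <- generator_config(n_per_group = c("TL" = 0, "EL-noASD" = 40, "EL-ASD" = 20),
                           cluster_spec = cs2, miss_rate = 0, seed = 2)
  co <- plant_clusters(cfg2)
  km <- kmeans(as.matrix(co$features[, averaged_feature_names()]), 2, nstart = 5)
  expect_equal(mclust::adjustedRandIndex(km$cluster, co$truth$cluster), 1.0)

  cs3 <- make_cluster_spec(5, separation = 3)
  cfg3 <- generator_config(n_per_group = c("TL" = 0, "EL-noASD" = 2, "EL-ASD" = 1),
                           cluster_spec = cs3, miss_rate = 0, seed = 2)
  expect_error(plant_clusters(cfg3), "more clusters")
})

test_that("sub-seed derivation is deterministic and label-sensitive", {
  expect_identical(derive_seed(7, "synth"), derive_seed(7, "synth"))
  expect_false(derive_seed(7, "synth") == derive_seed(7, "enet"))
  expect_false(derive_seed(7, "synth") == derive_seed(8, "synth"))
  s <- derive_seed(2^30, "anything")
  expect_true(s >= 1 && s < 2^31)
})
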