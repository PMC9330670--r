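#!/usr/bin/env Rscript
# Categorical arm: stratified 70/30 split, split-first EM imputation, GA
# wrapper feature selection (20 evolutions at desk scale; the study-scale
# configuration is 100 evolutions of a 50-chromosome population over 100
# generations), optimal and highest-incidence sets, top-down sets, holdout
# evaluation with bootstrap CIs, and shuffle tests against chance.

library(faceerp)
seed <- 20260924

el <- read.table("results/cohort.tsv", sep = "\t", header = TRUE,
                 check.names = FALSE)
el <- eligibility_filter(el[el$group != "TL", ])
split <- stratified_split(el$asd, 0.70, seed = seed)
main <- el[split$main, ]; hold <- el[split$holdout, ]
imp <- em_impute(main)
main <- imp$table
hold <- em_apply(hold, imp$model)
cat("Main sample n =", nrow(main), "; holdout n =", nrow(hold), "\n")

inv <- build_feature_inventory()
Xm <- as.matrix(main[, inv]); ym <- main$asd
Xh <- as.matrix(hold[, inv]); yh <- hold$asd

archive <- run_evolutions(Xm, ym, n_runs = 20, seed = seed,
                          pop_size = 18, generations = 12)
write.table(cbind(run = seq_along(archive$fitness),
                  fitness = archive$fitness, archive$masks * 1L),
            "results/ga_archive.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
opt <- optimal_mask(archive)
inc <- aggregate_incidence(archive)
cat("Best cross-validated AUC over evolutions:",
    round(max(archive$fitness), 3), "\n")
cat("Optimal set:", sum(opt), "features; gender/age selected in",
    round(100 * mean(archive$masks[, c("gender", "age")]), 1),
    "% of best masks\n")

masks <- c(list(optimal = opt),
           if (!inc$empty && any(inc$mask)) list(incidence = inc$mask),
           topdown_sets(inv))
metrics <- list()
for (nm in names(masks)) {
  if (!any(masks[[nm]])) next
  rep <- evaluate_holdout(Xm, ym, Xh, yh, masks[[nm]], n_boot = 2000,
                          seed = derive_seed(seed, nm))
  metrics[[nm]] <- cbind(set = nm, n_features = sum(masks[[nm]]), rep$metrics)
}
metr <- do.call(rbind, metrics); rownames(metr) <- NULL
write.table(metr, "results/classification_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
aucs <- metr[metr$metric == "auc", ]
cat("Holdout AUC (optimal set):",
    round(100 * aucs$value[aucs$set == "optimal"], 1), "% [",
    round(100 * aucs$lo[aucs$set == "optimal"], 1), ",",
    round(100 * aucs$hi[aucs$set == "optimal"], 1), "]\n")

X_all <- rbind(Xm, Xh); is_main <- c(rep(TRUE, nrow(Xm)), rep(FALSE, nrow(Xh)))
st <- shuffle_test(function(X, y)
  holdout_auc(X[is_main, , drop = FALSE], y[is_main],
              X[!is_main, , drop = FALSE], y[!is_main], opt),
  X_all, c(ym, yh), n_perm = 200, seed = derive_seed(seed, "shuffle"))
cat("Shuffle test vs chance (optimal set): p =", signif(st$p, 3), "\n")

write.table(data.frame(feature = inv[opt]), "results/flags_select.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
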