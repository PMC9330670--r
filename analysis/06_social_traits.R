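#!/usr/bin/env Rscript
# Dimensional arm: elastic-net prediction of the continuous social-skills
# outcome from the full feature inventory, leave-one-out outer CV with
# repeated inner 10-fold penalty selection, bootstrap CI on RMSE, and the
# strict always-selected feature stability rule.

library(faceerp)
seed <- 20260924

el <- read.table("results/imputed.tsv", sep = "\t", header = TRUE,
                 check.names = FALSE)
X <- as.matrix(el[, build_feature_inventory()])
y <- el$outcome

rep <- suppressWarnings(nested_cv_enet(
  X, y, alphas = c(0.5, 1), nlambda = 20, inner_k = 10, inner_reps = 2,
  n_boot = 1000, seed = seed))

cat(sprintf("RMSE = %.2f (95%% CI [%.2f, %.2f]), relative error = %.1f%%\n",
            rep$rmse, rep$rmse_ci[1], rep$rmse_ci[2],
            100 * rep$relative_error))
cat(sprintf("Pearson r(predicted, observed) = %.2f; slope t(%d) = %.2f, p = %.3g\n",
            rep$pearson_r, rep$slope$df, rep$slope$t, rep$slope$p))
cat(sprintf("Residual diagnostics: Shapiro p = %.2g, Breusch-Pagan p = %.2g\n",
            rep$shapiro_p, rep$breusch_pagan_p))
cat("Always-selected features:", nrow(rep$always_selected), "\n")

write.table(data.frame(rmse = rep$rmse, rmse_lo = rep$rmse_ci[1],
                       rmse_hi = rep$rmse_ci[2],
                       relative_error = rep$relative_error,
                       pearson_r = rep$pearson_r),
            "results/enet_metrics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(rep$always_selected, "results/enet_selected.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(feature = rep$always_selected$feature),
            "results/flags_enet.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
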