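#!/usr/bin/env Rscript
# Simulate the study cohort: 68 TL + 115 EL-no-ASD + 33 EL-ASD infants with
# the default planted group-by-condition effects, a linear social-outcome
# model, and 5% MCAR missingness on the ERP block.

library(faceerp)
seed <- 20260924
dir.create("results", showWarnings = FALSE)

cohort <- inject_missingness(
  generate_feature_table(generator_config(seed = seed)),
  0.05, "MCAR")
tab <- cohort$features

write.table(tab, "results/cohort.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Simulated", nrow(tab), "subjects;",
    sum(tab$group != "TL"), "EL of whom", sum(tab$asd), "EL-ASD (",
    round(100 * sum(tab$asd) / sum(tab$group != "TL"), 1), "% )\n")
cat("Missing ERP cells:",
    round(100 * mean(is.na(tab[, averaged_feature_names()])), 1), "%\n")

truth <- cohort$truth
effects <- do.call(rbind, lapply(truth$effects, function(e)
  data.frame(feature = e$feature_name, group = e$group, d = e$d)))
write.table(effects, "results/truth_effects.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Planted", nrow(effects), "group effects (written to results/truth_effects.tsv)\n")
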