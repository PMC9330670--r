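#!/usr/bin/env Rscript
# Group-level arm: for each of the 18 stimulus contrasts, a split-plot ANOVA
# with condition (the two contrast sides) as the within-subject factor and
# outcome group as the between factor; Sidak-corrected post-hoc tests with
# Cohen's d for contrasts with a significant condition-by-group interaction.

library(faceerp)

tab <- read.table("results/cohort.tsv", sep = "\t", header = TRUE,
                  check.names = FALSE)
cp <- faceerp:::contrast_parents()
rows <- list(); posthocs <- list()
for (nm in differential_feature_names()) {
  f <- faceerp:::parse_feature_name(nm)
  par <- cp[[f$suffix]]
  a <- paste(f$component, f$measure, par[1], sep = "_")
  b <- paste(f$component, f$measure, par[2], sep = "_")
  vals <- as.matrix(tab[, c(a, b)])
  keep <- complete.cases(vals)
  res <- suppressMessages(splitplot_anova(vals[keep, ], tab$group[keep]))
  int <- res[res$effect == "condition:group", ]
  rows[[nm]] <- cbind(feature = nm, int)
  if (is.finite(int$p) && int$p < 0.05) {
    posthocs[[nm]] <- cbind(feature = nm,
                            posthoc_table(tab[[nm]][keep], tab$group[keep]))
  }
}
anova_tab <- do.call(rbind, rows); rownames(anova_tab) <- NULL
write.table(anova_tab, "results/group_anova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- anova_tab$feature[anova_tab$p < 0.05]
cat("Condition x group interactions at p < .05:",
    paste(sig, collapse = ", "), "\n")
if (length(posthocs)) {
  ph <- do.call(rbind, posthocs); rownames(ph) <- NULL
  write.table(ph, "results/group_posthoc.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
}
write.table(data.frame(feature = sig), "results/flags_groupstats.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
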