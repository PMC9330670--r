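#!/usr/bin/env Rscript
# Cross-arm summary: which ERP features were flagged by the group-level
# ANOVA, the GA classifier, the elastic net, and the cluster
# characterization; features flagged by three or more arms are convergent.

library(faceerp)

flags <- list()
read_flags <- function(file) {
  if (!file.exists(file)) return(character(0))
  df <- read.table(file, sep = "\t", header = TRUE, check.names = FALSE)
  as.character(df$feature)
}
flags[["group-significant"]] <- read_flags("results/flags_groupstats.tsv")
flags[["GA-selected-optimal"]] <- read_flags("results/flags_select.tsv")
flags[["enet-selected"]] <- read_flags("results/flags_enet.tsv")
flags[["cluster-discriminating"]] <- read_flags("results/flags_bhc.tsv")

summary <- build_summary(flags)
write.table(summary, "results/summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Features flagged by any arm:", nrow(summary), "\n")
conv <- summary$feature[summary$convergent]
cat("Convergent (>= 3 arms):",
    if (length(conv)) paste(conv, collapse = ", ") else "none", "\n")
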