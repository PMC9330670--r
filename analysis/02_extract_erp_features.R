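#!/usr/bin/env Rscript
# Waveform-level demonstration: simulate stimulus-locked epochs for a small
# cohort, run artifact rejection + averaging + peak extraction, and verify
# that the extracted features recover the planted component parameters.

library(faceerp)
seed <- 20260924
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(
  n_per_group = c("TL" = 6, "EL-noASD" = 10, "EL-ASD" = 4),
  n_epochs = 40, noise_sd = 5, seed = seed)
cohort <- extract_cohort_features(generate_waveforms(cfg),
                                  abs_threshold_uV = 200, min_epochs = 10)
write.table(cohort$features, "results/waveform_features.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tp <- cohort$truth$waveform_params
err <- vapply(seq_len(nrow(tp)), function(i) {
  r <- tp[i, ]
  row <- cohort$features[cohort$features$subject == r$subject, ]
  abs(row[[paste0(r$component, "_lat_", r$condition)]] - r$latency)
}, numeric(1))
cat("Extracted ERP features for", nrow(cohort$features), "subjects\n")
cat("Median |latency error| vs planted:", round(median(err, na.rm = TRUE), 2),
    "ms at 40 epochs, 5 uV noise\n")
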