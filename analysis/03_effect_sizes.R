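#!/usr/bin/env Rscript
# Step 3: arm summaries, mGlass's delta effect sizes and response categories.
#
# Pools organoids across replicates, computes per-arm medians and SDs of the
# relative change in diameter and ΔORR, scores each treated arm against the
# control with the median-based Glass's delta, tests the arm contrast with a
# two-sided rank-sum test, and classifies each (arm, modality) with the
# validated treatment-class thresholds.

suppressMessages(library(orgresponse))

out <- "results/demo_run"
records <- read.csv(file.path(out, "organoid_records.csv"))

es <- effect_sizes_from_records(records)
th <- threshold_presets("methods")
es$predicted <- vapply(seq_len(nrow(es)), function(i) {
  classify_response(es$mglass_delta[i], th, modality = es$modality[i],
                    treatment_label = es$treatment_label[i])
}, "")
write.csv(es, file.path(out, "effect_sizes.csv"), row.names = FALSE)

cat("Effect sizes (vs control):\n")
print(es[c("treatment_label", "modality", "median_control",
           "median_treatment", "sd_control", "mglass_delta", "p_value",
           "predicted")], digits = 3)

comb <- tapply(seq_len(nrow(es)), es$treatment_label, function(i) {
  d <- es$predicted[i][es$modality[i] == "diameter"]
  o <- es$predicted[i][es$modality[i] == "ORR"]
  combine_modalities(if (length(d)) d else NA, if (length(o)) o else NA)
})
cat("\nCombined diameter + ΔORR categories (most-sensitive-wins):\n")
print(comb)
cat("\nEffect sizes written to", file.path(out, "effect_sizes.csv"), "\n")
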