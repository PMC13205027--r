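#!/usr/bin/env Rscript
# Step 4: concordance of organoid-predicted response with simulated clinical
# response.
#
# Simulates a 20-subject chemotherapy cohort: each subject's organoid line
# has a true diameter effect size, the organoid side predicts
# sensitive/intermediate/resistant with the chemo thresholds, and the
# clinical side draws a pre/post SLD pair through the calibrated link with
# measurement noise, mapped to RECIST v1.1. The cross-tabulation mirrors the
# structure of a clinical concordance analysis; with noise removed, every
# sensitive prediction corresponds to a clinical response by construction.

suppressMessages(library(orgresponse))

out <- "results/demo_run"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(2026)

n_subj <- 20
true_eff <- sort(stats::runif(n_subj, -0.6, 2.2), decreasing = TRUE)
subj <- sprintf("S%02d", seq_len(n_subj))
th <- threshold_presets("methods")

pred <- data.frame(
  subject_id = subj,
  predicted = vapply(true_eff, classify_response, "", thresholds = th,
                     modality = "diameter", treatment_label = "FOLFOX")
)
outs <- t(vapply(seq_len(n_subj), function(i) {
  simulate_clinical_outcome(true_eff[i], sld_pre = stats::rlnorm(1, log(80), 0.3),
                            noise_sd = 8)
}, c(sld_pre = 0, sld_post = 0)))
clin <- data.frame(subject_id = subj, sld_pre = outs[, 1], sld_post = outs[, 2])
clin$recist <- recist_category(clin$sld_pre, clin$sld_post)

ct <- concordance_table(pred, clin)
print(ct)

write.csv(cbind(pred, clin[-1]), file.path(out, "concordance_subjects.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(counts = as.data.frame.matrix(ct$counts),
       response_rate = as.list(round(ct$response_rate, 3)),
       note = "simulated subjects; SLD link and noise are synthetic stand-ins"),
  file.path(out, "concordance.json"), auto_unbox = TRUE, digits = NA)
cat("\nConcordance outputs written to", out, "\n")
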