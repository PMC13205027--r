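test_that("worked classification examples land in the documented categories", {
  th <- threshold_presets("methods")
  expect_equal(classify_response(1.32, th, modality = "diameter",
                                 treatment_label = "FOLFOX"), "sensitive")
  expect_equal(classify_response(0.82, th, modality = "diameter",
                                 treatment_label = "5FU+XRT"), "intermediate")
  # boundary inclusivity: diameter 1.25 "or higher" is sensitive
  expect_equal(classify_response(1.25, th, modality = "diameter",
                                 treatment_label = "FOLFOX"), "sensitive")
  # ΔORR chemo cutoff is strict: exactly 1.5 is not sensitive
  expect_equal(classify_response(1.5, th, modality = "ORR",
                                 treatment_label = "FOLFOX"), "intermediate")
  expect_equal(classify_response(1.51, th, modality = "ORR",
                                 treatment_label = "FOLFIRI"), "sensitive")
  # chemo diameter 0.75 "or lower" is resistant; ΔORR strict below 0
  expect_equal(classify_response(0.75, th, modality = "diameter",
                                 treatment_label = "FOLFOX"), "resistant")
  expect_equal(classify_response(0, th, modality = "ORR",
                                 treatment_label = "FOLFOX"), "intermediate")
  expect_equal(classify_response(-0.01, th, modality = "ORR",
                                 treatment_label = "FOLFOX"), "resistant")
  # chemoRT diameter: sensitive at 1 inclusive, resistant at 0 inclusive
  expect_equal(classify_response(1, th, modality = "diameter",
                                 treatment_label = "XRT"), "sensitive")
  expect_equal(classify_response(0, th, modality = "diameter",
                                 treatment_label = "5FU+XRT"), "resistant")
  expect_error(classify_response(1, th, modality = "diameter",
                                 treatment_label = "aspirin"), "known")
})

test_that("the alternative chemoRT diameter preset moves the resistant cutoff", {
  tr <- threshold_presets("results")
  expect_equal(classify_response(0.4, tr, modality = "diameter",
                                 treatment_label = "XRT"), "resistant")
  expect_equal(classify_response(0.4, threshold_presets("methods"),
                                 modality = "diameter",
                                 treatment_label = "XRT"), "intermediate")
})

test_that("threshold sets round-trip through their JSON config", {
  for (preset in c("methods", "results")) {
    th <- threshold_presets(preset)
    path <- file.path(withr::local_tempdir(), "thresholds.json")
    write_thresholds_json(th, path)
    back <- read_thresholds_json(path)
    expect_equal(as.data.frame(back), as.data.frame(th))
    expect_equal(attr(back, "preset"), preset)
    # classification decisions are identical under the re-read table
    for (x in c(-0.5, 0, 0.75, 1, 1.25, 1.4, 1.5, 2)) {
      expect_equal(classify_response(x, back, modality = "ORR",
                                     treatment_label = "XRT"),
                   classify_response(x, th, modality = "ORR",
                                     treatment_label = "XRT"))
    }
  }
  bad <- file.path(withr::local_tempdir(), "bad.json")
  jsonlite::write_json(list(thresholds = data.frame(
    modality = "diameter", treatment_class = "chemo",
    sensitive_cutoff = 0, sensitive_inclusive = TRUE,
    resistant_cutoff = 1, resistant_inclusive = TRUE)), bad)
  expect_error(read_thresholds_json(bad), "invalid")
})

test_that("classification is monotone non-decreasing in the effect size", {
  lv <- c(resistant = 1, intermediate = 2, sensitive = 3)
  set.seed(41)
  for (preset in c("methods", "results")) {
    th <- threshold_presets(preset)
    for (lab in c("FOLFOX", "FOLFIRI", "XRT", "5FU+XRT")) {
      for (mod in c("diameter", "ORR")) {
        x <- sort(stats::runif(60, -2, 3))
        cats <- vapply(x, classify_response, "", thresholds = th,
                       modality = mod, treatment_label = lab)
        expect_true(all(diff(lv[cats]) >= 0))
      }
    }
  }
})

test_that("modality combination is most-sensitive-wins, commutative, idempotent", {
  expect_equal(combine_modalities("sensitive", "intermediate"), "sensitive")
  expect_equal(combine_modalities("resistant", "resistant"), "resistant")
  expect_equal(combine_modalities("intermediate", NA), "intermediate")
  expect_equal(combine_modalities(NA, "resistant"), "resistant")
  expect_true(is.na(combine_modalities(NA, NA)))
  for (a in c("sensitive", "intermediate", "resistant")) {
    expect_equal(combine_modalities(a, a), a)
    for (b in c("sensitive", "intermediate", "resistant")) {
      expect_equal(combine_modalities(a, b), combine_modalities(b, a))
    }
  }
})

test_that("RECIST categories follow the SLD rules on worked examples", {
  expect_equal(recist_category(100, 69), "PR")    # -31%
  expect_equal(recist_category(100, 52), "PR")    # -48%
  expect_equal(recist_category(80, 80), "SD")
  expect_equal(recist_category(50, 0), "CR")
  expect_equal(recist_category(100, 125), "PD")   # +25%, +25 mm
  expect_equal(recist_category(10, 12.4), "SD")   # +24% but only +2.4 mm
  expect_equal(recist_category(10, 15), "PD")     # +50% and +5 mm
  expect_error(recist_category(0, 10), "sld_pre")
  expect_error(recist_category(10, -1), "sld_post")
})

test_that("RECIST agrees with an independent rule oracle on a pre/post lattice", {
  pre <- seq(5, 120, by = 5)
  post <- seq(0, 150, by = 2.5)
  for (p in pre) {
    got <- recist_category(rep(p, length(post)), post)
    want <- vapply(post, function(q) recist_oracle(p, q), "")
    expect_identical(got, want)
  }
})

test_that("concordance tables count subjects and rate PR/CR responses", {
  pred <- data.frame(subject_id = sprintf("S%02d", 1:14),
                     predicted = rep(c("sensitive", "intermediate"), each = 7))
  clin <- data.frame(subject_id = pred$subject_id,
                     recist = c(rep("PR", 7), "PR", "PR", "PR", "CR",
                                "SD", "SD", "PD"))
  ct <- concordance_table(pred, clin)
  expect_equal(ct$n, 14)
  expect_equal(unname(ct$response_rate["sensitive"]), 1)
  expect_equal(round(100 * unname(ct$response_rate["intermediate"]), 1), 57.1)
  expect_true(is.na(ct$response_rate["resistant"]))
  expect_equal(sum(ct$counts), 14)
  # RECIST derived from SLD columns when not supplied
  clin2 <- data.frame(subject_id = pred$subject_id,
                      sld_pre = 100, sld_post = c(rep(60, 11), rep(100, 3)))
  ct2 <- concordance_table(pred, clin2)
  expect_equal(unname(ct2$response_rate["sensitive"]), 1)
  # unmatched subjects are an error listing the ids
  expect_error(concordance_table(pred[-1, ], clin), "S01")
})
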