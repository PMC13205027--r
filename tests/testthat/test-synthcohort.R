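test_that("generate_cohort places every arm completely and reproducibly", {
  arms <- list(arm_spec("control", 30), arm_spec("FOLFOX", 30))
  spec <- small_spec(arms, fields = 2, replicates = 1)
  co <- generate_cohort(spec)
  expect_equal(as.vector(table(co$arm)[c("control", "FOLFOX")]), c(30L, 30L))
  # bit-for-bit determinism under the same spec + seed
  expect_identical(co, generate_cohort(spec))
  # one organoid per grid cell within a field: masks cannot overlap
  key <- paste(co$arm, co$replicate, co$field_index, co$cell_row, co$cell_col)
  expect_false(anyDuplicated(key) > 0)
  # geometry invariants
  expect_true(all(co$d0_um > 0))
  expect_true(all(co$d4_um[co$present_day4] > 0))
  expect_true(all(co$orr0 > 0 & co$orr0 < 1))
  expect_true(all(co$orr4 > 0 & co$orr4 < 1, na.rm = TRUE))
})

test_that("overfull arms fail with a placement error naming the arm", {
  arms <- list(arm_spec("crowded", 26))
  expect_error(generate_cohort(small_spec(arms, fields = 1, replicates = 1)),
               "crowded")
})

test_that("two arms with identical growth laws have matching empirical medians", {
  g <- law("normal", mean = 30, sd = 40)
  arms <- list(arm_spec("control", 500, growth_pct_law = g),
               arm_spec("same", 500, growth_pct_law = g))
  spec <- small_spec(arms, fields = 5, replicates = 4)
  co <- generate_cohort(spec)
  meds <- tapply(co$growth_pct, co$arm, stats::median)
  # zero-effect symmetry: difference within Monte-Carlo error of the median
  se <- 1.253 * 40 / sqrt(500)
  expect_lt(abs(meds[["control"]] - meds[["same"]]), 3 * sqrt(2) * se)
})

test_that("control-arm growth reproduces its generative median", {
  arms <- list(arm_spec("control", 1000,
                        growth_pct_law = law("normal", mean = 64.0, sd = 56.6)))
  spec <- small_spec(arms, fields = 5, replicates = 8)
  co <- generate_cohort(spec)
  expect_lt(abs(stats::median(co$growth_pct) - 64.0), 5)
})

test_that("attrition marks organoids absent at Day 4 without Day-4 fields", {
  arms <- list(arm_spec("control", 200, dropout_rate = 0.3))
  spec <- small_spec(arms, fields = 4, replicates = 2)
  co <- generate_cohort(spec)
  gone <- !co$present_day4
  expect_gt(sum(gone), 20)
  expect_true(all(is.na(co$d4_um[gone])))
  expect_true(all(is.na(co$delta_orr[gone])))
})

test_that("well luminescence follows the cubic viability-weighted model", {
  set.seed(1)
  # hand-computed: 100^3 + 200^3 + 300^3 = 3.6e7
  expect_equal(simulate_well_luminescence(c(100, 200, 300)), 3.6e7)
  # cubic scaling: doubling diameters multiplies luminescence by 8
  expect_equal(simulate_well_luminescence(c(200, 400, 600)) /
                 simulate_well_luminescence(c(100, 200, 300)), 8)
  # linear in viability
  expect_equal(simulate_well_luminescence(c(100, 200), viability = 0.5) /
                 simulate_well_luminescence(c(100, 200), viability = 1), 0.5)
  # empty well: noise floor only
  expect_equal(simulate_well_luminescence(numeric(0), noise_cv = 0,
                                          noise_floor = 0), 0)
  # monotone non-decreasing in every diameter
  expect_gt(simulate_well_luminescence(c(101, 200)),
            simulate_well_luminescence(c(100, 200)))
})

test_that("clinical outcome link is calibrated and deterministic", {
  # an effect mapped to -31% gives sld_post = 0.69 * sld_pre
  out <- simulate_clinical_outcome(31 / 35, sld_pre = 100)
  expect_equal(unname(out["sld_post"]), 69)
  # zero effect, zero noise: no SLD change
  out0 <- simulate_clinical_outcome(0, sld_pre = 80)
  expect_equal(unname(out0["sld_post"]), 80)
  # monotone: larger effect, smaller post SLD
  expect_lt(simulate_clinical_outcome(2, sld_pre = 100)["sld_post"],
            simulate_clinical_outcome(1, sld_pre = 100)["sld_post"])
  # same seed twice: identical noisy outputs
  a <- simulate_clinical_outcome(1, noise_sd = 5, seed = 99)
  b <- simulate_clinical_outcome(1, noise_sd = 5, seed = 99)
  expect_identical(a, b)
})
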