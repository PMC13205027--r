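test_that("noise-free rendering reproduces the true ORR from channel means", {
  arms <- list(arm_spec("control", 5,
                        orr0_law = law("constant", value = 0.5),
                        delta_orr_law = law("constant", value = 0.1)))
  spec <- small_spec(arms)
  co <- generate_cohort(spec)
  cp <- noise_free()
  fld <- render_field(co, day = 0, spec, cp, return_truth = TRUE)
  for (k in seq_len(nrow(co))) {
    m <- fld$truth_labels == k
    mn <- mean(fld$nadph[m]) - cp$fluor_background
    mf <- mean(fld$fad[m]) - cp$fluor_background
    # true ORR 0.5: background-subtracted channel means agree within 1%
    expect_lt(abs(mn / mf - 1), 0.01)
    expect_lt(abs(mn / (mn + mf) - 0.5), 0.005)
  }
  # Day 4 carries the shifted ORR
  fld4 <- render_field(co, day = 4, spec, cp, return_truth = TRUE)
  m <- fld4$truth_labels == 1
  mn <- mean(fld4$nadph[m]) - cp$fluor_background
  mf <- mean(fld4$fad[m]) - cp$fluor_background
  expect_lt(abs(mn / (mn + mf) - 0.6), 0.005)
})

test_that("an empty field is background plus noise only", {
  spec <- small_spec(list(arm_spec("control", 5)))
  co <- generate_cohort(spec)[0, ]
  cp <- channel_params()
  fld <- render_field(co, day = 0, spec, cp, seed = 3)
  expect_lt(abs(mean(fld$bf) - cp$bf_background), 1)
  expect_lt(abs(sd(as.numeric(fld$bf)) - cp$bf_noise_sd), 2)
  expect_lt(abs(mean(fld$nadph) - cp$fluor_background), 1)
})

test_that("a 300 um disk at 1.634 um/px renders with a 183-184 px long axis", {
  arms <- list(arm_spec("control", 1,
                        d0_diameter_law = law("constant", value = 300)))
  spec <- cohort_spec("TEST", arms, fields_per_replicate = 1, replicates = 1,
                      field_size_px = c(500L, 500L), pixel_size = 1.634,
                      grid_dim = 1, seed = 5)
  co <- generate_cohort(spec)
  co$ecc <- 1  # disk
  fld <- render_field(co, day = 0, spec, noise_free(), return_truth = TRUE)
  m <- fld$truth_labels == 1
  extent <- max(diff(range(which(rowSums(m) > 0))),
                diff(range(which(colSums(m) > 0)))) + 1
  expect_gte(extent, 183)
  expect_lte(extent, 184)
})

test_that("rendering is deterministic under a fixed seed", {
  spec <- small_spec(list(arm_spec("control", 10)))
  co <- generate_cohort(spec)
  a <- render_field(co, day = 0, spec, seed = 17)
  b <- render_field(co, day = 0, spec, seed = 17)
  expect_identical(a$bf, b$bf)
  expect_identical(a$nadph, b$nadph)
  expect_identical(a$fad, b$fad)
})

test_that("rendered organoid masks never overlap", {
  spec <- small_spec(list(arm_spec("control", 25)), grid_dim = 5)
  co <- generate_cohort(spec)
  fld <- render_field(co, day = 0, spec, noise_free(), return_truth = TRUE)
  areas <- tabulate(fld$truth_labels[fld$truth_labels > 0], nbins = 25)
  expect_true(all(areas > 0))
  # the truth label image is single-valued; overlap would have overwritten a
  # label, so every organoid must still cover (nearly) its full ellipse area
  for (k in seq_len(25)) {
    a_px <- co$d0_um[k] / spec$pixel_size / 2
    expect_gt(areas[k], 0.8 * pi * a_px^2 * co$ecc[k])
  }
})

test_that("TIFF round trip preserves channels and metadata", {
  spec <- small_spec(list(arm_spec("control", 4)))
  co <- generate_cohort(spec)
  fld <- render_field(co, day = 0, spec, seed = 2)
  path <- file.path(withr::local_tempdir(), "field.tiff")
  write_field_tiff(fld, path)
  back <- read_field_tiff(path)
  expect_identical(back$bf, fld$bf)
  expect_identical(back$nadph, fld$nadph)
  expect_identical(back$fad, fld$fad)
  expect_equal(back$pixel_size, fld$pixel_size)
  expect_equal(back$day, fld$day)
})
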