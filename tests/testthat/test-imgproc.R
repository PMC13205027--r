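test_that("disjoint organoids are segmented one-to-one with high Jaccard", {
  spec <- small_spec(list(arm_spec("control", 7)), grid_dim = 3)
  co <- generate_cohort(spec)
  fld <- render_field(co, day = 0, spec, noise_free(), return_truth = TRUE)
  seg <- segment_organoids(fld)
  expect_equal(seg$n_labels, 7)
  # match each truth object to the segmented label under its centre
  for (k in seq_len(7)) {
    tm <- fld$truth_labels == k
    hit <- seg$label_image[tm]
    lbl <- as.integer(names(which.max(table(hit[hit > 0]))))
    expect_gte(jaccard(tm, seg$label_image == lbl), 0.95)
  }
})

test_that("a blank field yields zero labels, not an error", {
  spec <- small_spec(list(arm_spec("control", 5)))
  co <- generate_cohort(spec)[0, ]
  fld <- render_field(co, day = 0, spec, seed = 9)   # background + noise only
  seg <- segment_organoids(fld)
  expect_equal(seg$n_labels, 0)
  # and a perfectly constant image as well
  fld$bf[] <- 1200L
  expect_equal(segment_organoids(fld)$n_labels, 0)
})

test_that("touching disks are split by the watershed into two labels", {
  n <- 300
  bf <- matrix(3000L, n, n)
  m <- disk_mask(n, 100, 150, 50) | disk_mask(n, 200, 150, 50)  # tangent
  bf[m] <- 1500L
  fld <- structure(list(bf = bf, nadph = bf, fad = bf, pixel_size = 1.634,
                        day = 0, field_index = 1L, replicate = 1L,
                        arm = "x", line_id = "x", clipped_ids = character(0)),
                   class = "field_image")
  seg <- segment_organoids(fld)
  expect_equal(seg$n_labels, 2)
})

test_that("segmentation is invariant to rescaling the brightfield intensity", {
  spec <- small_spec(list(arm_spec("control", 6)), grid_dim = 3)
  co <- generate_cohort(spec)
  fld <- render_field(co, day = 0, spec, seed = 4)
  seg1 <- segment_organoids(fld)
  fld$bf <- fld$bf * 3L
  seg2 <- segment_organoids(fld)
  expect_identical(seg1$label_image, seg2$label_image)
})

test_that("leading-edge mask is the outer band of the object", {
  n <- 201
  lab <- matrix(0L, n, n)
  lab[disk_mask(n, 101, 101, 50)] <- 1L
  edge <- leading_edge_mask(lab, 1, width_px = 20)
  # annulus area fraction (50^2 - 30^2) / 50^2 = 0.64 up to discretization
  frac <- sum(edge) / sum(lab == 1)
  expect_lt(abs(frac - 0.64), 0.03)
  # band is inside the label
  expect_true(all(lab[edge] == 1L))
  # a thin object yields its full mask
  lab2 <- matrix(0L, 61, 61)
  lab2[disk_mask(61, 31, 31, 15)] <- 1L
  expect_identical(leading_edge_mask(lab2, 1, 20), lab2 == 1L)
  # unknown label errors by name
  expect_error(leading_edge_mask(lab, 7), "7")
})

test_that("leading edge never exceeds the band width (distance-transform check)", {
  spec <- small_spec(list(arm_spec("control", 4)))
  co <- generate_cohort(spec)
  fld <- render_field(co, day = 0, spec, noise_free())
  seg <- segment_organoids(fld)
  for (k in seq_len(seg$n_labels)) {
    edge <- leading_edge_mask(seg$label_image, k, width_px = 10)
    expect_true(all(seg$label_image[edge] == k))
    dm <- EBImage::distmap(seg$label_image == k)
    expect_lte(max(dm[edge]), 10)
  }
})

test_that("background normalization removes the field background", {
  # constant field: everything is background, result all zeros
  ch <- matrix(400, 200, 200)
  bgm <- matrix(TRUE, 200, 200)
  expect_true(all(background_normalize(ch, bgm) == 0))
  # plateau B + S over background B recovers S
  ch[50:80, 50:80] <- 400 + 250
  bgm2 <- ch == 400
  norm <- background_normalize(ch, bgm2)
  expect_equal(unique(norm[!bgm2]), 250)
  expect_equal(attr(norm, "background_level"), 400)
  # idempotent on its own noise-free output
  norm2 <- background_normalize(norm, bgm2)
  expect_equal(as.numeric(norm2), as.numeric(norm))
  # division mode
  div <- background_normalize(ch, bgm2, method = "divide")
  expect_equal(unique(div[!bgm2]), 650 / 400)
  # too-small background region
  expect_error(background_normalize(ch, matrix(FALSE, 200, 200)), "background")
})

test_that("background level is estimated within median error on noisy fields", {
  set.seed(8)
  ch <- matrix(stats::rnorm(300 * 300, 400, 20), 300, 300)
  bgm <- matrix(TRUE, 300, 300)
  norm <- background_normalize(ch, bgm)
  expect_lt(abs(attr(norm, "background_level") - 400), 2)
})
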