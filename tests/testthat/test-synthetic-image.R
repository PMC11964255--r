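test_that("phantom images are bit-identical under the same seed", {
  cfg <- phantom_image_config(field_size_um = 4, seed = 9L)
  g1 <- generate_fibril_image(cfg)
  g2 <- generate_fibril_image(cfg)
  expect_identical(g1$image$heights, g2$image$heights)
  expect_identical(g1$labels, g2$labels)
  g3 <- generate_fibril_image(phantom_image_config(field_size_um = 4,
                                                   seed = 10L))
  expect_false(identical(g1$image$heights, g3$image$heights))
})

test_that("ground-truth labels follow the generating parameters", {
  # no banding depth -> every ROI labelled banding-absent
  flat <- generate_fibril_image(phantom_image_config(field_size_um = 4,
                                                     dband_depth = 0, seed = 2))
  expect_true(all(flat$labels$dbanding == 0))

  # heavy blur crosses both the clarity and banding cutoffs
  blurry <- generate_fibril_image(phantom_image_config(
    field_size_um = 4, blur_sigma_nm = 45, seed = 2))
  expect_true(all(blurry$labels$clarity == 0))
  expect_true(all(blurry$labels$dbanding == 0))

  # orientation label mirrors the mode
  ali <- generate_fibril_image(phantom_image_config(
    field_size_um = 4, orientation_mode = "aligned", seed = 2))
  expect_true(all(ali$labels$random_orientation == 0))

  # kinks mark exactly the ROIs holding a kink vertex
  kk <- generate_fibril_image(phantom_image_config(
    field_size_um = 6, kink_prob = 1, n_fibrils = 6, seed = 3))
  kxy <- attr(kk$labels, "kink_xy_nm")
  in_field <- kxy[, 1] >= 0 & kxy[, 1] < 6000 & kxy[, 2] >= 0 & kxy[, 2] < 6000
  expected_kinked <- unique(paste(floor(kxy[in_field, 2] / 1000),
                                  floor(kxy[in_field, 1] / 1000)))
  got_kinked <- with(kk$labels, paste(roi_row, roi_col)[linearity == 0])
  expect_setequal(got_kinked, expected_kinked)
})

test_that("banded fibril profiles repeat at the configured 67 nm period", {
  # near-horizontal aligned fibrils; the image row through the apex of a
  # fibril samples its axial banding profile
  cfg <- phantom_image_config(field_size_um = 6, n_fibrils = 4,
                              orientation_mode = "aligned",
                              aligned_axis_deg = 0, dband_depth = 0.5,
                              noise_sigma_nm = 0, seed = 12)
  g <- generate_fibril_image(cfg)
  h <- g$image$heights
  px_nm <- g$image$px_size_nm
  apex_rows <- order(apply(h, 1, max), decreasing = TRUE)[1:3]
  periods <- vapply(apex_rows, function(r) {
    oracle_profile_period(h[r, ], px_nm)
  }, numeric(1))
  expect_equal(mean(periods), 67, tolerance = 0.05)
})

test_that("configuration invariants are enforced", {
  expect_error(phantom_image_config(field_size_um = 1.3, px_per_um = 51),
               "integer pixel grid")
  expect_error(phantom_image_config(dband_depth = 1.5), "\\[0, 1\\]")
  expect_error(phantom_image_config(n_fibrils = 0), "at least one fibril")
})
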