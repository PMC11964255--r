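test_that("preprocessing removes affine baselines, is idempotent and scale-free", {
  s <- generate_ftir_spectrum(spectrum_config("native"))
  p <- preprocess_spectrum(s)

  # adding a linear ramp leaves the rubber-band output unchanged
  ramped <- as_ftir_spectrum(s$wavenumbers_cm1,
                             s$absorbance + 0.3 + 2e-4 * (s$wavenumbers_cm1 - 800))
  p_r <- preprocess_spectrum(ramped)
  expect_equal(p_r$absorbance, p$absorbance, tolerance = 1e-8)

  # idempotence: preprocessing a preprocessed spectrum changes nothing
  p2 <- preprocess_spectrum(p)
  expect_equal(p2$absorbance, p$absorbance, tolerance = 1e-8)

  # any positive scale factor gives the same normalized output
  scaled <- as_ftir_spectrum(s$wavenumbers_cm1, 7.3 * s$absorbance)
  expect_equal(preprocess_spectrum(scaled)$absorbance, p$absorbance,
               tolerance = 1e-10)

  # steps are logged
  expect_true(any(grepl("baseline", p$preprocessing_log)))
  expect_true(any(grepl("normalize", p$preprocessing_log)))
})

test_that("band metrics recover the generator's configuration", {
  # native: peaks near 1630/1540 and the Amide III triplet
  s <- generate_ftir_spectrum(spectrum_config("native"))
  m <- band_metrics(preprocess_spectrum(s))
  expect_equal(m$amideI_peak_cm1, 1630, tolerance = 5 / 1630)
  expect_equal(m$amideII_peak_cm1, 1540, tolerance = 5 / 1540)
  expect_true(m$amideIII_triplet_present)
  expect_false(m$denatured_signature)
  expect_equal(m$amideIII_positions_cm1, c(1205, 1235, 1280), tolerance = 0.01)

  # configured I:II amplitude ratio 1.6 is recovered from peak heights
  expect_equal(m$amideI_II_ratio, 1.6, tolerance = 0.05)

  # denatured: Amide I shifted to ~1640, triplet gone
  d <- generate_ftir_spectrum(spectrum_config("denatured"))
  md <- band_metrics(preprocess_spectrum(d))
  expect_gte(md$amideI_peak_cm1, 1637)
  expect_false(md$amideIII_triplet_present)
  expect_true(md$denatured_signature)

  # a non-collagen trace (single band far from Amide I) has no Amide I peak
  w <- seq(800, 4000, by = 2)
  odd <- as_ftir_spectrum(w, exp(-0.5 * ((w - 2900) / 80)^2))
  # rejected either at baseline normalization (no amide-region intensity)
  # or at peak detection
  expect_error(band_metrics(odd),
               "no Amide I intensity|not a collagen-like spectrum")

  # band metrics invariant to scale and additive baseline of the raw input
  raw <- generate_ftir_spectrum(spectrum_config("native", noise_sd = 0.002,
                                                seed = 8))
  tilted <- as_ftir_spectrum(raw$wavenumbers_cm1,
                             3 * raw$absorbance + 0.1 +
                               1e-4 * (raw$wavenumbers_cm1 - 800))
  m1 <- band_metrics(preprocess_spectrum(raw))
  m2 <- band_metrics(preprocess_spectrum(tilted))
  expect_equal(m1$amideI_II_ratio, m2$amideI_II_ratio, tolerance = 1e-6)
  expect_identical(m1$amideIII_triplet_present, m2$amideIII_triplet_present)
})

test_that("triplet detection survives noise at 10% of the Amide III amplitude", {
  # weakest sub-band amplitude is 0.13 of Amide I
  hits <- vapply(1:100, function(s) {
    sp <- generate_ftir_spectrum(spectrum_config("native", noise_sd = 0.013,
                                                 seed = s))
    band_metrics(preprocess_spectrum(sp))$amideIII_triplet_present
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("ratio comparisons use the rank-sum test", {
  same <- c(1.60, 1.61, 1.59, 1.60, 1.62)
  out <- compare_ratios(same, same)
  expect_gt(out$p_value, 0.9)
  expect_equal(out$diff_means, 0)

  # a 50% ratio shift is detected at n = 10 per group
  set.seed(9)
  a <- 1.6 + rnorm(10, 0, 0.05)
  b <- 2.4 + rnorm(10, 0, 0.05)
  expect_lt(compare_ratios(a, b)$p_value, 0.05)
  expect_error(compare_ratios(1:2, same), ">= 3")
})
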