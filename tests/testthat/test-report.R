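# Desk-scale pipeline runs: small fields and few replicates so the whole
# file stays within a couple of minutes.

small_cfg <- function(groups, seed = 7L, out = NULL) {
  experiment_config(groups, seed = seed, n_images = 1L, n_curves = 8L,
                    n_decays = 1L, n_spectra = 3L, decay_photons = 5e4,
                    training_field_um = 6, output_dir = out)
}

base_img <- phantom_image_config(field_size_um = 6, seed = 0L)
# the emulated wet-sterilization degradation is partial -- blur and noise
# just beyond the label cutoffs (30 nm / 2 nm), banding removed, kinks in
# most fibrils -- mirroring scans that stay analyzable despite degradation
degraded_img <- phantom_image_config(field_size_um = 6, dband_depth = 0,
                                     blur_sigma_nm = 32, kink_prob = 0.8,
                                     noise_sigma_nm = 2.5, seed = 0L)

test_that("a null experiment shows zero change and no exceedances", {
  g <- experiment_group("DD", control_image = base_img,
                        irradiated_image = base_img,
                        control_E_GPa = 4.8, irradiated_E_GPa = 4.8)
  res <- run_pipeline(small_cfg(list(g)))
  expect_length(res$failed, 0)
  expect_true(all(res$table2_change$change_pct == 0))
  expect_false(any(res$table2_change$exceeds))
})

test_that("the degraded-pair emulation flags banding, clarity and linearity", {
  g <- experiment_group("WS", control_image = base_img,
                        irradiated_image = degraded_img,
                        control_E_GPa = 5.27, irradiated_E_GPa = 8.10)
  res <- run_pipeline(small_cfg(list(g), seed = 11L))
  expect_length(res$failed, 0)
  ct <- res$table2_change
  flag <- function(mt) ct$exceeds[ct$metric == mt]
  expect_true(flag("dbanding"))
  expect_true(flag("clarity"))
  expect_true(flag("linearity"))
  expect_false(flag("random_orientation"))
  # degradation decreases banding/clarity prevalence and increases kinking
  expect_lt(ct$change_pct[ct$metric == "dbanding"], 0)
  expect_lt(ct$change_pct[ct$metric == "clarity"], 0)
  expect_gt(ct$change_pct[ct$metric == "linearity"], 0)   # kinked% change

  # mechanics summary reflects the configured stiffening with significance
  irr_row <- res$table4_moduli[res$table4_moduli$member == "irradiated", ]
  expect_equal(irr_row$variation_pct, 100 * (8.10 - 5.27) / 5.27,
               tolerance = 0.05)
  expect_true(irr_row$significant)
})

test_that("reruns with an identical config reproduce every table exactly", {
  g <- experiment_group("DT", control_image = base_img,
                        irradiated_image = degraded_img)
  cfg <- small_cfg(list(g), seed = 3L)
  r1 <- run_pipeline(cfg)
  r2 <- run_pipeline(cfg)
  expect_identical(r1$table1_consistency, r2$table1_consistency)
  expect_identical(r1$table2_change, r2$table2_change)
  expect_identical(r1$table3_prevalence, r2$table3_prevalence)
  expect_identical(r1$table4_moduli, r2$table4_moduli)
  expect_identical(r1$fig5_lifetimes, r2$fig5_lifetimes)

  # output files land in the requested directory
  out <- withr::local_tempdir()
  run_pipeline(small_cfg(list(g), seed = 3L, out = out))
  expect_true(file.exists(file.path(out, "table2_change.tsv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
})
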