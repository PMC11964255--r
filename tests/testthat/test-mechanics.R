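test_that("contact point is detected at the configured offset", {
  fc <- generate_force_curve(force_curve_config(5, contact_offset_nm = 25))
  spacing <- median(diff(fc$distance_nm))
  expect_equal(find_contact_point(fc), 25, tolerance = 2 * spacing)

  # constant force offset leaves detection unchanged (baseline-relative rule)
  fc_off <- fc
  fc_off$force_nN <- fc$force_nN + 5
  expect_equal(find_contact_point(fc_off), find_contact_point(fc))

  flat <- as_force_curve(seq(0, 50, length.out = 100), rep(0, 100))
  expect_error(find_contact_point(flat), "no contact detected")
})

test_that("Hertz fit recovers the generating modulus", {
  # noiseless round trip at the dry diagnostic control value
  fit <- fit_hertz_pyramid(generate_force_curve(force_curve_config(4.82)))
  expect_true(fit$converged)
  expect_equal(fit$E_GPa, 4.82, tolerance = 1e-3)

  # scaling all forces by 2 doubles the fitted modulus
  fc <- generate_force_curve(force_curve_config(3, force_noise_nN = 0.3,
                                                seed = 4))
  fc2 <- fc
  fc2$force_nN <- 2 * fc$force_nN
  e1 <- fit_hertz_pyramid(fc)$E_GPa
  e2 <- fit_hertz_pyramid(fc2)$E_GPa
  expect_equal(e2, 2 * e1, tolerance = 1e-6)

  # fitted E invariant to the pre-contact baseline length
  ea <- fit_hertz_pyramid(generate_force_curve(
    force_curve_config(5, contact_offset_nm = 10)))$E_GPa
  eb <- fit_hertz_pyramid(generate_force_curve(
    force_curve_config(5, contact_offset_nm = 60)))$E_GPa
  expect_equal(ea, eb, tolerance = 1e-4)

  # the two prefactor conventions differ by ~5%
  fcs <- generate_force_curve(force_curve_config(5))
  es <- fit_hertz_pyramid(fcs, prefactor = "sqrt2")$E_GPa
  eb2 <- fit_hertz_pyramid(fcs, prefactor = "bilodeau")$E_GPa
  expect_equal(es / eb2, 0.7453 * sqrt(2), tolerance = 1e-3)
})

test_that("noisy Monte-Carlo recovery is unbiased within 2%", {
  Es <- vapply(1:20, function(s) {
    fit_hertz_pyramid(generate_force_curve(
      force_curve_config(5, force_noise_nN = 1, seed = s)))$E_GPa
  }, numeric(1))
  expect_equal(mean(Es), 5, tolerance = 0.02)
})

test_that("group summaries report medians and paired variation", {
  fits <- lapply(c(3, 4, 5), function(E) {
    fit_hertz_pyramid(generate_force_curve(force_curve_config(E)))
  })
  gs <- summarize_group(fits, group_id = "ctrl")
  expect_equal(gs$median_GPa, 4, tolerance = 1e-3)
  expect_equal(gs$n, 3)

  ctrl <- summarize_group(c(3.8, 4.0, 4.2), group_id = "c")
  irr <- summarize_group(c(4.8, 5.0, 5.2), paired_control = ctrl,
                         group_id = "r")
  expect_equal(irr$variation_pct, 25)
  expect_error(summarize_group(numeric(0)), "no converged fits")
})

test_that("rank-sum test matches exact references and the enumeration oracle", {
  # identical groups: U = n1 n2 / 2, p ~ 1
  rs <- rank_sum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(rs$U, 8)
  expect_gt(rs$p_value, 0.95)

  # complete separation of 3 vs 3: exact two-sided p = 0.1
  rs2 <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(rs2$U, 0)
  expect_equal(rs2$p_value, 0.1)

  # random tie-free data matches the full enumeration oracle exactly
  set.seed(11)
  for (rep in 1:5) {
    a <- round(rnorm(4), 6)
    b <- round(rnorm(4) + 0.5, 6)
    expect_equal(rank_sum_test(a, b)$p_value, oracle_ranksum_exact(a, b))
  }
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("Kruskal-Wallis H matches stats::kruskal.test, Dunn flags shifts", {
  set.seed(21)
  gs <- list(rnorm(8), rnorm(7), c(rnorm(6), rnorm(2)))  # with near-ties
  gs[[2]][1] <- gs[[1]][1]                                # exact tie
  kw <- kruskal_wallis_dunn(gs)
  ref <- stats::kruskal.test(gs)
  expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(kw$p_value, ref$p.value, tolerance = 1e-10)

  # identical groups: H ~ 0, all adjusted p ~ 1
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  kw0 <- kruskal_wallis_dunn(same)
  expect_equal(kw0$H, 0, tolerance = 1e-12)
  expect_true(all(kw0$pairs$p_adjusted > 0.99))

  # one group shifted by 10 SDs is flagged in both its pairs
  set.seed(5)
  shifted <- list(rnorm(20), rnorm(20), rnorm(20) + 10)
  kw1 <- kruskal_wallis_dunn(shifted)
  p13 <- kw1$pairs$p_adjusted[kw1$pairs$group_i == 1 & kw1$pairs$group_j == 3]
  p23 <- kw1$pairs$p_adjusted[kw1$pairs$group_i == 2 & kw1$pairs$group_j == 3]
  p12 <- kw1$pairs$p_adjusted[kw1$pairs$group_i == 1 & kw1$pairs$group_j == 2]
  expect_lt(p13, 0.05)
  expect_lt(p23, 0.05)
  expect_gt(p12, 0.05)
  expect_error(kruskal_wallis_dunn(list(1:3, 4:6)), "rank_sum_test")
})
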