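test_that("average lifetime is the amplitude-weighted mean", {
  expect_equal(average_lifetime(c(1, 0, 0), c(5, 1, 1)), 5)
  expect_equal(average_lifetime(c(1, 1, 1), c(3, 6, 9)), 6)
  expect_equal(average_lifetime(c(0.5, 0.3, 0.2), c(0.5, 2, 6)), 2.05)
  # invariant to uniform amplitude rescaling
  expect_equal(average_lifetime(10 * c(0.5, 0.3, 0.2), c(0.5, 2, 6)), 2.05)
  expect_error(average_lifetime(c(0, 0, 0), c(1, 2, 3)), "all amplitudes")
})

test_that("decay generator produces Poisson counts around the analytic integral", {
  cfg <- decay_config(c(0.5, 0.3, 0.2), c(0.5, 2, 6), n_photons = 1e6,
                      seed = 3)
  h <- generate_decay_histogram(cfg)
  # total counts within 4 sqrt(n)
  expect_lt(abs(h$total_photons - 1e6), 4 * sqrt(1e6))

  # expected bin means match an independent numerical integral of the
  # tri-exponential intensity
  lam <- attr(h, "expected")
  bw <- cfg$bin_width_ps / 1000
  idx <- c(1, 10, 100, 1000)
  num <- vapply(idx, function(i) {
    stats::integrate(function(t) {
      0.5 * exp(-t / 0.5) + 0.3 * exp(-t / 2) + 0.2 * exp(-t / 6)
    }, (i - 1) * bw, i * bw, rel.tol = 1e-12)$value
  }, numeric(1))
  # ratios of expected means equal ratios of the independent integrals
  # (the generator only fixes the overall normalization)
  expect_equal(lam[idx] / lam[1], num / num[1], tolerance = 1e-9)

  # observed counts consistent with Poisson law where means are large
  big <- lam > 100
  z <- (h$counts[big] - lam[big]) / sqrt(lam[big])
  expect_lt(max(abs(z)), 6)
  expect_lt(abs(mean(z)), 0.2)

  # single-exponential config: log expected means linear in t
  h1 <- generate_decay_histogram(decay_config(c(1, 0, 0), c(2, 1, 1),
                                              n_photons = 1e5, seed = 1))
  lam1 <- attr(h1, "expected")
  sl <- diff(log(lam1[1:100]))
  expect_equal(sl, rep(sl[1], 99), tolerance = 1e-9)
  expect_equal(sl[1], -0.05 / 2, tolerance = 1e-9)  # -bin/tau

  expect_error(decay_config(c(0, 0, 0), c(1, 2, 3)), "amplitude")
  expect_error(decay_config(c(1, 0, 0), c(1, 2, 3), bin_width_ps = 48),
               "integer bin count")
})

test_that("tri-exponential fit recovers the generating parameters", {
  # noiseless: feed the exact expected means as counts
  cfg <- decay_config(c(0.6, 0.3, 0.1), c(0.4, 2.5, 7), n_photons = 1e6,
                      seed = 1)
  h <- generate_decay_histogram(cfg)
  hn <- as_decay_histogram(h$bin_centers_ns, round(attr(h, "expected")),
                           h$bin_width_ps)
  fit <- fit_triexponential(hn)
  truth <- average_lifetime(c(0.6, 0.3, 0.1), c(0.4, 2.5, 7))
  expect_true(fit$converged)
  expect_equal(fit$avg_lifetime_ns, truth, tolerance = 0.005)

  # Eq-2 consistency to machine precision and ascending lifetimes
  expect_equal(fit$avg_lifetime_ns,
               sum(fit$amplitudes * fit$lifetimes_ns) / sum(fit$amplitudes))
  expect_true(!is.unsorted(fit$lifetimes_ns))

  # determinism: identical histogram -> identical fit
  fit2 <- fit_triexponential(hn)
  expect_identical(fit$lifetimes_ns, fit2$lifetimes_ns)
  expect_identical(fit$amplitudes, fit2$amplitudes)

  # single-exponential input: degenerate components merge, tau_bar within 1%
  h1 <- generate_decay_histogram(decay_config(c(1, 0, 0), c(3, 1, 1),
                                              n_photons = 1e6, seed = 4))
  f1 <- fit_triexponential(h1)
  expect_equal(f1$avg_lifetime_ns, 3, tolerance = 0.01)

  # count floor enforced
  tiny <- generate_decay_histogram(decay_config(c(1, 0, 0), c(3, 1, 1),
                                                n_photons = 100, seed = 1))
  expect_error(fit_triexponential(tiny), "below")
})

test_that("lifetime summaries report integer percent changes vs paired controls", {
  mk <- function(tau) structure(list(amplitudes = c(1, 0, 0),
                                     lifetimes_ns = c(tau, 1, 1),
                                     avg_lifetime_ns = tau,
                                     chi2_reduced = 1, converged = TRUE),
                                class = "tri_exp_fit")
  fits <- list(
    CDS = lapply(c(5.60, 5.67, 5.74), mk),
    RDS = lapply(c(5.95, 6.02, 6.09), mk)
  )
  out <- summarize_lifetimes(fits, pairing = c(RDS = "CDS"))
  expect_equal(out$mean_ns, c(5.67, 6.02), tolerance = 1e-12)
  expect_equal(out$percent_change[out$condition == "RDS"], 6)

  fits2 <- list(CWS = list(mk(5.75)), RWS = list(mk(5.44)))
  out2 <- summarize_lifetimes(fits2, pairing = c(RWS = "CWS"))
  expect_equal(out2$percent_change[out2$condition == "RWS"], -5)

  # identical means -> 0%
  fits3 <- list(a = list(mk(5)), b = list(mk(5)))
  expect_equal(summarize_lifetimes(fits3, c(b = "a"))$percent_change[2], 0)
})
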