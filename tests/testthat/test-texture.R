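test_that("patching yields non-overlapping row-major 51 px ROIs", {
  img <- as_afm_image(matrix(rnorm(510 * 510), 510, 510), 1000 / 51, "t")
  rois <- patch_image(img)
  expect_length(rois, 100)
  expect_identical(rois[[1]]$origin, c(row = 0L, col = 0L))
  expect_identical(rois[[2]]$origin, c(row = 0L, col = 1L))   # row-major
  expect_identical(rois[[11]]$origin, c(row = 1L, col = 0L))
  expect_identical(rois[[1]]$pixels, img$heights[1:51, 1:51])

  # a single-ROI image returns itself
  one <- as_afm_image(matrix(1:2601, 51, 51), 1000 / 51)
  expect_identical(patch_image(one)[[1]]$pixels, one$heights)

  # non-multiple dimensions crop to the largest 51-multiple with a warning
  odd <- as_afm_image(matrix(rnorm(520 * 515), 520, 515), 1000 / 51)
  expect_warning(rois2 <- patch_image(odd), "cropping")
  expect_length(rois2, 100)

  tiny <- as_afm_image(matrix(0, 30, 30), 1000 / 51)
  expect_error(patch_image(tiny), "smaller than one")
})

test_that("features behave on degenerate, banded and rotated ROIs", {
  # constant patch: the all-zero vector by convention
  fz <- extract_features(matrix(5, 51, 51))
  expect_true(all(fz == 0))

  # paired phantoms (same seed => same geometry): banded ROIs carry
  # strictly more spectral power at the banding frequency
  gb <- generate_fibril_image(phantom_image_config(field_size_um = 4,
                                                   dband_depth = 0.5, seed = 5))
  gu <- generate_fibril_image(phantom_image_config(field_size_um = 4,
                                                   dband_depth = 0, seed = 5))
  cov_idx <- which(gb$labels$covered == 1)[1:5]
  fb <- roi_features(patch_image(gb$image)[cov_idx])
  fu <- roi_features(patch_image(gu$image)[cov_idx])
  expect_true(all(fb[, "psd_dband_ratio"] > fu[, "psd_dband_ratio"]))

  # rotation by 90 degrees leaves the rotation-invariant descriptors
  # unchanged within numerical tolerance
  roi <- patch_image(gb$image)[[cov_idx[1]]]
  m <- roi$pixels
  m90 <- t(m)[, nrow(m):1]
  f1 <- extract_features(m)
  f2 <- extract_features(m90)
  inv <- c(paste0("psd_r", 1:6), "psd_dband", "psd_dband_ratio",
           "spec_entropy", "coh_mean", "orient_circvar", "spec_orient_R",
           "axis2_frac", "axis2_circvar", "height_sd")
  expect_equal(f1[inv], f2[inv], tolerance = 1e-6)
})

test_that("spectral features are translation-invariant for periodic textures", {
  xs <- outer(seq_len(51), seq_len(51), function(i, j) {
    10 * sin(2 * pi * i / 3.4) + 5 * sin(2 * pi * j / 10)
  })
  shift <- rbind(xs[18:51, ], xs[1:17, ])   # circular shift: same spectrum
  f1 <- extract_features(xs)
  f2 <- extract_features(shift)
  spec <- c(paste0("psd_r", 1:6), "psd_dband", "spec_entropy")
  expect_equal(f1[spec], f2[spec], tolerance = 1e-8)
})

test_that("LDA training separates, replays and degrades as expected", {
  set.seed(31)
  # two well-separated clouds: 100% training accuracy
  X <- rbind(matrix(rnorm(200, 0), 50), matrix(rnorm(200, 6), 50))
  y <- rep(c(0, 1), each = 50)
  fit <- train_metric_classifier(X, y, "sep")
  expect_equal(mean(predict(fit, X) == y), 1)

  # duplicated training set -> identical model
  fit2 <- train_metric_classifier(rbind(X, X), c(y, y), "sep")
  expect_equal(fit$projection_weights, fit2$projection_weights,
               tolerance = 1e-10)
  expect_equal(fit$decision_threshold, fit2$decision_threshold,
               tolerance = 1e-10)

  # permuted labels: training accuracy near the majority-class rate
  set.seed(32)
  Xr <- matrix(rnorm(500 * 8), 500)
  yr <- sample(rep(c(0, 1), c(300, 200)))
  fitr <- train_metric_classifier(Xr, yr, "null")
  acc <- mean(predict(fitr, Xr) == yr)
  expect_lt(abs(acc - 0.6), 0.07)

  expect_error(train_metric_classifier(X, rep(1, 100), "one-class"),
               "one-class")
})

test_that("leave-one-out consistency equals the brute-force oracle", {
  set.seed(41)
  for (n in c(8, 24)) {
    X <- matrix(rnorm(n * 4), n)
    y <- rep_len(c(0, 1), n)
    X[y == 1, 1] <- X[y == 1, 1] + 1.5   # partly separable
    rep_pkg <- loo_consistency(X, y, "m")
    correct <- vapply(seq_len(n), function(i) {
      oracle_lda_predict(X[-i, , drop = FALSE], y[-i],
                         X[i, , drop = FALSE]) == y[i]
    }, logical(1))
    expect_equal(rep_pkg$consistency_pct, 100 * mean(correct))
    expect_identical(rep_pkg$threshold_pct, 100 - rep_pkg$consistency_pct)
  }

  # perfectly separable: consistency 100, threshold 0
  Xs <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 8), 10))
  ys <- rep(c(0, 1), each = 10)
  rp <- loo_consistency(Xs, ys, "sep")
  expect_equal(rp$consistency_pct, 100)
  expect_equal(rp$threshold_pct, 0)
})

test_that("label agreement is percent matching", {
  a <- rep(c(0, 1), 350)
  expect_equal(label_agreement(a, a, "m")$consistency_pct, 100)
  expect_equal(label_agreement(a, 1 - a, "m")$consistency_pct, 0)
  b <- a; b[1:350] <- 1 - b[1:350]
  r <- label_agreement(a, b, "m")
  expect_equal(r$consistency_pct, 50)
  expect_equal(r$threshold_pct, 50)
  expect_error(label_agreement(a, a[-1], "m"), "length")
})

test_that("prevalence pools by counts and change tables flag exceedances", {
  set.seed(51)
  X <- rbind(matrix(rnorm(80, 0), 20), matrix(rnorm(80, 5), 20))
  y <- rep(c(0, 1), each = 20)
  clf <- list(linearity = train_metric_classifier(X, y, "linearity"))

  all_pos <- matrix(rnorm(40, 5), 10)
  pt <- prevalence_table(clf, all_pos)
  expect_equal(pt$prevalence_pct, 100)
  expect_equal(pt$kinked_pct, 0)

  # pooling two disjoint subsets is the count-weighted mean
  A <- matrix(rnorm(6 * 4, 5), 6)
  B <- matrix(rnorm(18 * 4, 0), 18)
  pA <- prevalence_table(clf, A)$prevalence_pct
  pB <- prevalence_table(clf, B)$prevalence_pct
  pAB <- prevalence_table(clf, rbind(A, B))$prevalence_pct
  expect_equal(pAB, (6 * pA + 18 * pB) / 24, tolerance = 1e-10)

  th <- c(dbanding = 14, clarity = 16, random_orientation = 6, linearity = 7)
  cp <- c(dbanding = 73, clarity = 69, random_orientation = 97, linearity = 92)
  ip <- c(dbanding = 57, clarity = 41, random_orientation = 95, linearity = 83)
  ct <- change_table(cp, ip, th)
  # antisymmetry of the change column
  ct_rev <- change_table(ip, cp, th)
  expect_equal(ct$change_pct, -ct_rev$change_pct)
  # identical prevalences: zero change, no exceedances
  ct0 <- change_table(cp, cp, th)
  expect_true(all(ct0$change_pct == 0) && !any(ct0$exceeds))
  expect_error(change_table(cp, ip[-1], th), "missing metric")
})
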