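#' Patch an AFM image into 1 um regions of interest
#'
#' Subdivides the height map into non-overlapping 51 x 51 px ROIs in
#' row-major order (0-based, top-left origin, half-open extents). A
#' 510 x 510 image yields exactly 100 ROIs. Images whose dimensions are
#' not multiples of 51 are cropped top-left to the largest multiple with
#' a warning (resampling would alter pixel-exact texture).
#'
#' @param image an `afm_image` of at least 51 x 51 px.
#' @return list of `roi` objects; each has `pixels` (51 x 51), `origin`
#'   (0-based `c(row, col)`), `parent_id`, and carries `px_size_nm` as an
#'   attribute.
#' @export
patch_image <- function(image) {
  stopifnot(inherits(image, "afm_image"))
  roi_px <- collafib_constants$roi_px
  h <- image$heights
  if (nrow(h) < roi_px || ncol(h) < roi_px) {
    stopf("image (%d x %d) smaller than one %d px ROI",
          nrow(h), ncol(h), roi_px)
  }
  nr <- nrow(h) %/% roi_px
  nc <- ncol(h) %/% roi_px
  if (nr * roi_px != nrow(h) || nc * roi_px != ncol(h)) {
    warning(sprintf("cropping %d x %d image to top-left %d x %d",
                    nrow(h), ncol(h), nr * roi_px, nc * roi_px),
            call. = FALSE)
  }
  out <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      k <- k + 1L
      rows <- ((i - 1L) * roi_px + 1L):(i * roi_px)
      cols <- ((j - 1L) * roi_px + 1L):(j * roi_px)
      roi <- structure(
        list(pixels = h[rows, cols],
             origin = c(row = i - 1L, col = j - 1L),
             parent_id = image$id),
        class = "roi"
      )
      attr(roi, "px_size_nm") <- image$px_size_nm
      out[[k]] <- roi
    }
  }
  out
}

#' Spatial-spectral texture features of a 1 um ROI
#'
#' Deterministic fixed-schema descriptor vector combining:
#' \itemize{
#'   \item radially averaged 2-D power-spectral density in six annular
#'     frequency bands plus a dedicated band around the D-band frequency
#'     (1/67 nm^-1) and its peak-to-background ratio;
#'   \item structure-tensor orientation statistics: mean coherence and
#'     circular variance of the (doubled) orientation angle;
#'   \item gradient-contrast statistics pooled over radius-6 px
#'     neighborhoods (clarity/edge strength);
#'   \item ridge-curvature statistics: energy-weighted spatial variation
#'     of the orientation field (kinked vs straight fibrils).
#' }
#' Spectral fractions are normalized by total AC power and contrast terms
#' by the ROI height scale, so the schema is scale-robust. A constant ROI
#' returns the all-zero vector by convention.
#'
#' @param roi a `roi` from [patch_image()] (or a bare 51 x 51 matrix).
#' @param neighborhood_radius_px pooling radius for local contrast
#'   (default 6).
#' @param px_size_nm pixel pitch; taken from the ROI attribute when
#'   present (default 1000/51).
#' @return Named numeric feature vector (fixed length and order).
#' @export
extract_features <- function(roi, neighborhood_radius_px = 6,
                             px_size_nm = NULL) {
  if (inherits(roi, "roi")) {
    if (is.null(px_size_nm)) px_size_nm <- attr(roi, "px_size_nm")
    m <- roi$pixels
  } else {
    m <- roi
  }
  if (is.null(px_size_nm)) px_size_nm <- 1000 / 51
  stopifnot(is.matrix(m))
  n <- nrow(m)

  feat_names <- c(paste0("psd_r", 1:6), "psd_dband", "psd_dband_ratio",
                  "spec_entropy", "coh_mean", "orient_circvar",
                  "orient_cos4", "orient_sin4",
                  "spec_orient_R", "spec_orient_cos2", "spec_orient_sin2",
                  "grad_mean", "grad_sd", "grad_p90", "contrast_norm",
                  "local_sd_mean", "local_sd_sd",
                  "curv_mean", "curv_p90", "axis2_frac", "axis2_circvar",
                  "height_sd")
  if (stats::sd(as.numeric(m)) == 0) {
    return(stats::setNames(numeric(length(feat_names)), feat_names))
  }

  # --- radial power spectrum ---
  mz <- m - mean(m)
  F2 <- Mod(stats::fft(mz))^2
  fx <- (seq_len(n) - 1) / n
  fx <- ifelse(fx > 0.5, fx - 1, fx)         # signed frequencies, cycles/px
  fr <- sqrt(outer(fx^2, fx^2, "+"))
  ac <- fr > 0
  total <- sum(F2[ac])
  psd_bins <- numeric(6)
  edges <- seq(0, 0.5 * sqrt(2), length.out = 7)
  for (b in 1:6) {
    sel <- ac & fr > edges[b] & fr <= edges[b + 1]
    psd_bins[b] <- if (any(sel)) sum(F2[sel]) / total else 0
  }
  f_dband <- px_size_nm / collafib_constants$dband_period_nm  # cycles/px
  band <- ac & fr >= 0.8 * f_dband & fr <= 1.2 * f_dband
  psd_dband <- if (any(band)) sum(F2[band]) / total else 0
  mean_band <- if (any(band)) mean(F2[band]) else 0
  mean_bg <- mean(F2[ac & !band])
  psd_dband_ratio <- if (mean_bg > 0) mean_band / mean_bg else 0
  p <- F2[ac] / total
  p <- p[p > 0]
  spec_entropy <- -sum(p * log(p)) / log(sum(ac))

  # angular concentration of the low-frequency spectrum (below the
  # banding frequency): a straight fibril's cross-sectional envelope
  # concentrates along one axis through the origin, so the doubled-angle
  # resultant is high for a single fibril axis and low for several
  phi <- atan2(matrix(fx, n, n, byrow = FALSE),  # fy varies by row
               matrix(fx, n, n, byrow = TRUE))   # fx varies by column
  low <- ac & fr <= 0.6 * px_size_nm / collafib_constants$dband_period_nm
  if (any(low)) {
    Pw <- F2[low]
    ph <- phi[low]
    spw <- sum(Pw)
    spec_orient_cos2 <- sum(Pw * cos(2 * ph)) / spw
    spec_orient_sin2 <- sum(Pw * sin(2 * ph)) / spw
    spec_orient_R <- sqrt(spec_orient_cos2^2 + spec_orient_sin2^2)
  } else {
    spec_orient_cos2 <- 0; spec_orient_sin2 <- 0; spec_orient_R <- 0
  }

  # --- gradients of the raw ROI (contrast / clarity terms) ---
  gx <- matrix(0, n, n); gy <- matrix(0, n, n)
  gx[, 2:(n - 1)] <- (m[, 3:n] - m[, 1:(n - 2)]) / 2
  gy[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2

  # --- structure tensor on a low-passed ROI ---
  # The banding modulation adds axial gradients orthogonal to the
  # cross-fibril ones; the two populations cancel in the tensor and
  # destroy coherence. Low-pass filtering just below the banding period
  # leaves the fibril envelope only, so coherence and orientation track
  # the fibril axis.
  sigma_lp <- 0.5 * collafib_constants$dband_period_nm / px_size_nm
  mlp <- gaussian_blur(m, sigma_lp)
  gxl <- matrix(0, n, n); gyl <- matrix(0, n, n)
  gxl[, 2:(n - 1)] <- (mlp[, 3:n] - mlp[, 1:(n - 2)]) / 2
  gyl[2:(n - 1), ] <- (mlp[3:n, ] - mlp[1:(n - 2), ]) / 2
  Jxx <- box_mean(gxl * gxl, neighborhood_radius_px)
  Jyy <- box_mean(gyl * gyl, neighborhood_radius_px)
  Jxy <- box_mean(gxl * gyl, neighborhood_radius_px)
  tr <- Jxx + Jyy
  det_term <- sqrt(pmax(0, (Jxx - Jyy)^2 + 4 * Jxy^2))
  coh <- ifelse(tr > 1e-12, det_term / tr, 0)
  # gate orientation statistics to energetic (fibril) pixels so that
  # near-empty ROIs do not report the orientation noise of flat background
  gate <- tr >= 0.05 * max(tr)
  w_energy <- ifelse(gate, tr, 0)
  sw <- sum(w_energy)
  coh_mean <- if (sw > 0) sum(coh * w_energy) / sw else 0

  # Orientation statistics on the QUADRUPLED gradient angle: a banded
  # fibril produces two orthogonal gradient populations (cross-section
  # vs axial banding) whose doubled angles cancel; modulo 90 degrees
  # they coincide, so 4*theta identifies the fibril axis.
  theta <- atan2(gy, gx)
  w_g <- gx^2 + gy^2
  swg <- sum(w_g)
  c4 <- cos(4 * theta); s4 <- sin(4 * theta)
  if (swg > 0) {
    orient_cos4 <- sum(w_g * c4) / swg
    orient_sin4 <- sum(w_g * s4) / swg
    orient_circvar <- 1 - sqrt(orient_cos4^2 + orient_sin4^2)
  } else {
    orient_cos4 <- 0; orient_sin4 <- 0; orient_circvar <- 0
  }
  # curvature below tracks the doubled-angle tensor orientation field
  # of the low-passed ROI (smooth along straight fibrils, discontinuous
  # at kinks and crossings)
  theta2 <- atan2(2 * Jxy, Jxx - Jyy)
  cx <- cos(theta2); sx <- sin(theta2)

  # --- gradient contrast pooled over radius-r neighborhoods ---
  gmag <- sqrt(gx^2 + gy^2)
  pooled <- box_mean(gmag, neighborhood_radius_px)
  hsd <- stats::sd(as.numeric(m))
  grad_mean <- mean(pooled)
  grad_sd <- stats::sd(as.numeric(pooled))
  grad_p90 <- stats::quantile(pooled, 0.9, names = FALSE)
  contrast_norm <- grad_mean / hsd
  local_m2 <- box_mean(m * m, neighborhood_radius_px)
  local_sd <- sqrt(pmax(0, local_m2 - box_mean(m, neighborhood_radius_px)^2))
  local_sd_mean <- mean(local_sd)
  local_sd_sd <- stats::sd(as.numeric(local_sd))

  # --- ridge curvature: spatial variation of the orientation field ---
  dcx <- matrix(0, n, n); dsx <- matrix(0, n, n)
  dcx[, 2:(n - 1)] <- (cx[, 3:n] - cx[, 1:(n - 2)]) / 2
  dsx[, 2:(n - 1)] <- (sx[, 3:n] - sx[, 1:(n - 2)]) / 2
  dcy <- matrix(0, n, n); dsy <- matrix(0, n, n)
  dcy[2:(n - 1), ] <- (cx[3:n, ] - cx[1:(n - 2), ]) / 2
  dsy[2:(n - 1), ] <- (sx[3:n, ] - sx[1:(n - 2), ]) / 2
  curv <- sqrt(dcx^2 + dsx^2 + dcy^2 + dsy^2)
  curv_mean <- if (sw > 0) sum(curv * w_energy) / sw else 0
  curv_p90 <- if (any(gate)) stats::quantile(curv[gate], 0.9, names = FALSE) else 0

  # secondary-axis statistics on the low-passed tensor axis field:
  # axis2_frac is the energy fraction deviating > 15 degrees of axis
  # (30 degrees of doubled angle) from the ROI's dominant axis, and
  # axis2_circvar the energy-weighted circular variance of the doubled
  # angle. Both are ~0 for one straight fibril and rise when a kink
  # splits the energy between two arm directions.
  if (sw > 0) {
    c2m <- sum(w_energy * cx) / sw
    s2m <- sum(w_energy * sx) / sw
    axis2_circvar <- 1 - sqrt(c2m^2 + s2m^2)
    mu2 <- atan2(s2m, c2m)
    dev_cos <- cos(theta2 - mu2)
    axis2_frac <- sum(w_energy[dev_cos < cos(30 * pi / 180)]) / sw
  } else { axis2_frac <- 0; axis2_circvar <- 0 }

  out <- c(psd_bins, psd_dband, psd_dband_ratio, spec_entropy,
           coh_mean, orient_circvar, orient_cos4, orient_sin4,
           spec_orient_R, spec_orient_cos2, spec_orient_sin2,
           grad_mean, grad_sd, grad_p90, contrast_norm,
           local_sd_mean, local_sd_sd,
           curv_mean, curv_p90, axis2_frac, axis2_circvar, hsd)
  stats::setNames(out, feat_names)
}

# stack a list of feature vectors (or pass a matrix through)
feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  do.call(rbind, features)
}

#' Train a binary LDA classifier for one morphometry metric
#'
#' Two-class linear discriminant analysis with a shrinkage-regularized
#' pooled covariance: a ridge of `lda_ridge * mean(diag(S))` is added to
#' the diagonal so the covariance is positive-definite even on small or
#' collinear training sets. Priors are the empirical class frequencies.
#' The decision rule is `w . x >= c` with `w = S^-1 (mu1 - mu0)` and
#' `c = w . (mu0 + mu1)/2 - log(pi1/pi0)`; boundary ties go to the
#' positive class. The stored fields alone reproduce every prediction.
#'
#' @param features list of feature vectors or a numeric matrix (rows =
#'   ROIs).
#' @param labels binary vector (0/1 or logical), one per ROI.
#' @param metric name of the morphometry metric being learned.
#' @param ridge ridge fraction (default `collafib_constants$lda_ridge`).
#' @param prior `"empirical"` (class frequencies enter the threshold) or
#'   `"balanced"` (equal priors). Balanced priors are used for prevalence
#'   estimation: with empirical priors a rare class (e.g. kinked ROIs)
#'   is majority-voted away and prevalence shifts go undetected.
#' @return A `metric_classifier`.
#' @export
train_metric_classifier <- function(features, labels,
                                    metric = "unnamed",
                                    ridge = collafib_constants$lda_ridge,
                                    prior = c("empirical", "balanced")) {
  prior <- match.arg(prior)
  X <- feature_matrix(features)
  y <- as.integer(labels)
  if (length(y) != nrow(X)) stopf("features and labels differ in length")
  if (!all(y %in% c(0L, 1L))) stopf("labels must be binary for '%s'", metric)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n0 < 2 || n1 < 2) {
    stopf("metric '%s': need >= 2 examples per class (got %d/%d)",
          metric, n0, n1)
  }
  mu0 <- colMeans(X[y == 0L, , drop = FALSE])
  mu1 <- colMeans(X[y == 1L, , drop = FALSE])
  X0 <- sweep(X[y == 0L, , drop = FALSE], 2, mu0)
  X1 <- sweep(X[y == 1L, , drop = FALSE], 2, mu1)
  # MLE normalization (divide by n, not n-2): duplicating the training
  # set then reproduces the identical model, and the scale difference is
  # absorbed by the discriminant threshold
  S <- (crossprod(X0) + crossprod(X1)) / (n0 + n1)
  md <- mean(diag(S))
  lam <- if (md > 0) ridge * md else 1e-8
  S_reg <- S + diag(lam, ncol(X))
  w <- solve(S_reg, mu1 - mu0)
  thr <- sum(w * (mu0 + mu1)) / 2 -
    if (prior == "empirical") log(n1 / n0) else 0
  structure(
    list(metric = metric,
         class_means = rbind(neg = mu0, pos = mu1),
         pooled_covariance = S_reg, ridge_added = lam,
         prior_mode = prior,
         priors = c(neg = n0 / (n0 + n1), pos = n1 / (n0 + n1)),
         projection_weights = as.numeric(w),
         decision_threshold = thr,
         feature_names = colnames(X)),
    class = "metric_classifier"
  )
}

#' Predict with a trained metric classifier
#'
#' @param object a `metric_classifier`.
#' @param newdata feature matrix or list of feature vectors.
#' @param ... unused.
#' @return Integer 0/1 predictions (ties at the boundary -> 1).
#' @export
predict.metric_classifier <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)
  scores <- as.numeric(X %*% object$projection_weights)
  as.integer(scores >= object$decision_threshold)
}

new_consistency_report <- function(metric, consistency_pct, n, method) {
  stopifnot(consistency_pct >= 0, consistency_pct <= 100)
  structure(
    list(metric = metric, consistency_pct = consistency_pct,
         threshold_pct = 100 - consistency_pct, n_rois = n, method = method),
    class = "consistency_report"
  )
}

#' Leave-one-out consistency of a metric classifier
#'
#' Iterates through every ROI, trains on the remaining n-1 and predicts
#' the held-out one; consistency is the percent predicted correctly and
#' the change-detection threshold is exactly `100 - consistency`.
#'
#' @inheritParams train_metric_classifier
#' @return A `consistency_report`: `metric`, `consistency_pct`,
#'   `threshold_pct`, `n_rois`, `method`.
#' @export
loo_consistency <- function(features, labels, metric = "unnamed",
                            ridge = collafib_constants$lda_ridge,
                            prior = c("empirical", "balanced")) {
  prior <- match.arg(prior)
  X <- feature_matrix(features)
  y <- as.integer(labels)
  n <- nrow(X)
  if (n < 3) stopf("need >= 3 examples")
  if (length(unique(y)) < 2) stopf("metric '%s': both classes required", metric)
  correct <- logical(n)
  for (i in seq_len(n)) {
    fit <- train_metric_classifier(X[-i, , drop = FALSE], y[-i],
                                   metric = metric, ridge = ridge,
                                   prior = prior)
    correct[i] <- predict(fit, X[i, , drop = FALSE]) == y[i]
  }
  new_consistency_report(metric, 100 * mean(correct), n, "loo-cv")
}

#' Agreement between two label sets
#'
#' Percent agreement between two equal-length binary labellings (e.g. a
#' relabelling session versus the original), as a `consistency_report`.
#'
#' @param labels_a,labels_b binary vectors of equal length.
#' @param metric metric name.
#' @return A `consistency_report` with `method = "relabel-agreement"`.
#' @export
label_agreement <- function(labels_a, labels_b, metric = "unnamed") {
  a <- as.integer(labels_a); b <- as.integer(labels_b)
  if (length(a) != length(b)) stopf("label sets differ in length")
  if (length(a) == 0) stopf("empty label sets")
  if (!all(c(a, b) %in% 0:1)) stopf("labels must be binary")
  new_consistency_report(metric, 100 * mean(a == b), length(a),
                         "relabel-agreement")
}

#' Per-metric prevalence of positive predictions in a sample
#'
#' Applies the four trained metric classifiers to every ROI of one sample
#' and reports the percent predicted positive. For linearity both
#' `linear%` and `kinked% = 100 - linear%` are reported, matching the
#' bookkeeping of the change table.
#'
#' @param classifiers named list of `metric_classifier`s (names are the
#'   metrics).
#' @param rois list of `roi` objects, or a precomputed feature matrix.
#' @param neighborhood_radius_px passed to [extract_features()].
#' @return data.frame: `metric`, `prevalence_pct`, `n_rois`, plus an
#'   extra `kinked_pct` column filled for the `linearity` row.
#' @export
prevalence_table <- function(classifiers, rois, neighborhood_radius_px = 6) {
  stopifnot(is.list(classifiers), !is.null(names(classifiers)))
  if (is.matrix(rois)) {
    X <- rois
  } else {
    if (length(rois) == 0) stopf("empty ROI list")
    X <- feature_matrix(lapply(rois, extract_features,
                               neighborhood_radius_px = neighborhood_radius_px))
  }
  res <- lapply(names(classifiers), function(mt) {
    pred <- predict(classifiers[[mt]], X)
    prev <- 100 * mean(pred)
    data.frame(metric = mt, prevalence_pct = prev, n_rois = nrow(X),
               kinked_pct = if (mt == "linearity") 100 - prev else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Control-versus-irradiated change table with exceedance flags
#'
#' Per metric: `change = irradiated - control` prevalence, compared with
#' the metric's threshold; `exceeds = |change| > threshold`. Linearity
#' prevalences are supplied as `linear%` and the change is computed on
#' `kinked% = 100 - linear%`, so an increase in kinking is a positive
#' change.
#'
#' @param control_prev,irradiated_prev named numeric vectors of
#'   prevalence percentages over the same metrics.
#' @param thresholds named numeric vector of threshold percentages (e.g.
#'   `threshold_pct` from [loo_consistency()] reports).
#' @return data.frame of class `change_table`: `metric`,
#'   `control_prevalence_pct`, `irradiated_prevalence_pct`, `change_pct`,
#'   `threshold_pct`, `exceeds`.
#' @export
change_table <- function(control_prev, irradiated_prev, thresholds) {
  metrics <- names(control_prev)
  if (is.null(metrics)) stopf("prevalence vectors must be named by metric")
  missing_m <- setdiff(metrics, names(irradiated_prev))
  if (length(missing_m)) stopf("missing metric(s): %s",
                               paste(missing_m, collapse = ", "))
  missing_t <- setdiff(metrics, names(thresholds))
  if (length(missing_t)) stopf("missing threshold(s): %s",
                               paste(missing_t, collapse = ", "))
  if (any(control_prev < 0 | control_prev > 100) ||
      any(irradiated_prev < 0 | irradiated_prev > 100)) {
    stopf("prevalences must be in [0, 100]")
  }
  rows <- lapply(metrics, function(mt) {
    cp <- control_prev[[mt]]; ip <- irradiated_prev[[mt]]
    if (mt == "linearity") {
      chg <- (100 - ip) - (100 - cp)   # change in kinked%
    } else {
      chg <- ip - cp
    }
    th <- thresholds[[mt]]
    data.frame(metric = mt, control_prevalence_pct = cp,
               irradiated_prevalence_pct = ip, change_pct = chg,
               threshold_pct = th, exceeds = abs(chg) > th,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("change_table", class(out))
  out
}
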