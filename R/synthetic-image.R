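#' Configuration for a synthetic AFM fibril image
#'
#' Describes a square height-map phantom of collagen fibrils: anti-aliased
#' thick polylines with a semicircular height cross-section, axial
#' D-banding as a cosine height modulation, optional per-fibril kinks,
#' degradation blur and additive height noise. Overlapping fibrils
#' composite by maximum height (AFM topography records the tallest
#' surface).
#'
#' Ground-truth labels for every 1 um region of interest (ROI) follow the
#' cutoffs in [collafib_constants] and depend only on the generating
#' geometry, never on rendered pixels.
#'
#' @param field_size_um physical edge length in um (default 10).
#' @param px_per_um sampling density (default 51; 10 um -> 510 px so each
#'   1 um ROI is exactly 51 px).
#' @param n_fibrils number of fibrils (default 14).
#' @param fibril_width_nm full fibril width (default 220).
#' @param fibril_height_nm apex height (default 40).
#' @param dband_period_nm axial banding period (default 67, the canonical
#'   collagen repeat).
#' @param dband_depth fractional height-modulation amplitude in [0, 1]
#'   (default 0.35).
#' @param orientation_mode `"random"` or `"aligned"`.
#' @param aligned_axis_deg mean axis for aligned mode (jitter SD 4 deg).
#' @param kink_prob per-fibril probability of one abrupt direction change.
#' @param blur_sigma_nm degradation blur SD (default 0).
#' @param noise_sigma_nm additive height-noise SD (default 0.5).
#' @param seed integer seed.
#' @return A `phantom_image_config` list.
#' @export
phantom_image_config <- function(field_size_um = 10, px_per_um = 51,
                                 n_fibrils = 14, fibril_width_nm = 220,
                                 fibril_height_nm = 40,
                                 dband_period_nm = 67, dband_depth = 0.35,
                                 orientation_mode = c("random", "aligned"),
                                 aligned_axis_deg = 0, kink_prob = 0,
                                 blur_sigma_nm = 0, noise_sigma_nm = 0.5,
                                 seed = 1L) {
  orientation_mode <- match.arg(orientation_mode)
  check_number(field_size_um, "field_size_um", positive = TRUE)
  check_number(px_per_um, "px_per_um", positive = TRUE)
  n_px <- field_size_um * px_per_um
  if (abs(n_px - round(n_px)) > 1e-9) {
    stopf("field_size_um * px_per_um must give an integer pixel grid")
  }
  check_number(n_fibrils, "n_fibrils", nonneg = TRUE)
  if (n_fibrils < 1) stopf("need at least one fibril for a labelled phantom")
  for (nm in c("fibril_width_nm", "fibril_height_nm", "dband_period_nm")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  if (dband_depth < 0 || dband_depth > 1) stopf("dband_depth must be in [0, 1]")
  if (kink_prob < 0 || kink_prob > 1) stopf("kink_prob must be in [0, 1]")
  check_number(blur_sigma_nm, "blur_sigma_nm", nonneg = TRUE)
  check_number(noise_sigma_nm, "noise_sigma_nm", nonneg = TRUE)
  structure(
    list(field_size_um = field_size_um, px_per_um = px_per_um,
         n_fibrils = as.integer(n_fibrils),
         fibril_width_nm = fibril_width_nm,
         fibril_height_nm = fibril_height_nm,
         dband_period_nm = dband_period_nm, dband_depth = dband_depth,
         orientation_mode = orientation_mode,
         aligned_axis_deg = aligned_axis_deg, kink_prob = kink_prob,
         blur_sigma_nm = blur_sigma_nm, noise_sigma_nm = noise_sigma_nm,
         seed = as.integer(seed)),
    class = "phantom_image_config"
  )
}

#' Construct an AFM image object
#'
#' @param heights numeric matrix of surface heights in nm (no NAs).
#' @param px_size_nm physical pixel pitch in nm (> 0).
#' @param id free-text provenance.
#' @return An `afm_image` list.
#' @export
as_afm_image <- function(heights, px_size_nm, id = "") {
  if (!is.matrix(heights) || any(!is.finite(heights))) {
    stopf("heights must be a finite numeric matrix")
  }
  check_number(px_size_nm, "px_size_nm", positive = TRUE)
  structure(list(heights = heights, px_size_nm = px_size_nm, id = id),
            class = "afm_image")
}

# distance to segment + axial coordinate, vectorized over pixel coords
seg_render <- function(px, py, p0, p1, s0) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  L <- sqrt(vx^2 + vy^2)
  ux <- vx / L; uy <- vy / L
  dx <- px - p0[1]; dy <- py - p0[2]
  t <- dx * ux + dy * uy
  tc <- pmin(pmax(t, 0), L)
  ddx <- dx - tc * ux; ddy <- dy - tc * uy
  list(dist = sqrt(ddx^2 + ddy^2), s = s0 + tc, len = L)
}

#' Generate a synthetic AFM fibril image with ground-truth ROI labels
#'
#' Renders the configured fibrils into a height map and derives the
#' four binary morphometry labels (clarity, D-banding, random
#' orientation, linearity) for every 1 um ROI directly from the
#' generating parameters:
#' \itemize{
#'   \item `dbanding` is 1 iff `dband_depth >= dband_depth_min` and
#'     `blur_sigma_nm <= dband_blur_max_nm`;
#'   \item `clarity` is 1 iff blur and noise are at or below their cutoffs;
#'   \item `random_orientation` mirrors `orientation_mode`;
#'   \item `linearity` is 1 unless a kink vertex falls inside the ROI.
#' }
#' Same config and seed give bit-identical output.
#'
#' @param config a [phantom_image_config()].
#' @return list with `image` (an `afm_image`) and `labels` (data.frame:
#'   `roi_row`, `roi_col` 0-based, `clarity`, `dbanding`,
#'   `random_orientation`, `linearity`, all 0/1, plus `covered` -- a
#'   geometry-derived flag marking ROIs actually traversed by a fibril,
#'   useful for building balanced evaluation sets).
#' @export
generate_fibril_image <- function(config) {
  stopifnot(inherits(config, "phantom_image_config"))
  cst <- collafib_constants
  n_px <- as.integer(round(config$field_size_um * config$px_per_um))
  px_nm <- 1000 / config$px_per_um
  field_nm <- config$field_size_um * 1000
  # pixel-center coordinates (x = col, y = row), nm
  xs <- (seq_len(n_px) - 0.5) * px_nm
  px <- rep(xs, each = n_px)    # column-major over (row, col): x varies by col
  py <- rep(xs, times = n_px)
  dim_flat <- c(n_px, n_px)

  half_w <- config$fibril_width_nm / 2
  H <- config$fibril_height_nm
  P <- config$dband_period_nm
  depth <- config$dband_depth

  fibrils <- local_seed(config$seed, {
    lapply(seq_len(config$n_fibrils), function(i) {
      anchor <- stats::runif(2, 0, field_nm)
      phi <- if (config$orientation_mode == "random") {
        stats::runif(1, 0, pi)
      } else {
        (config$aligned_axis_deg + stats::rnorm(1, 0, 4)) * pi / 180
      }
      kinked <- stats::runif(1) < config$kink_prob
      dphi <- if (kinked) {
        sample(c(-1, 1), 1) * stats::runif(1, 35, 60) * pi / 180
      } else 0
      band_phase <- stats::runif(1, 0, P)
      list(anchor = anchor, phi = phi, kinked = kinked, dphi = dphi,
           band_phase = band_phase)
    })
  })

  L <- 2 * field_nm * sqrt(2)   # long enough to always span the field
  heights <- matrix(0, n_px, n_px)
  kink_xy <- matrix(numeric(0), ncol = 2)
  for (fb in fibrils) {
    u <- c(cos(fb$phi), sin(fb$phi))
    if (fb$kinked) {
      # kink at the anchor; two half-segments with different directions
      u2 <- c(cos(fb$phi + fb$dphi), sin(fb$phi + fb$dphi))
      segs <- list(list(p0 = fb$anchor - u * L / 2, p1 = fb$anchor, s0 = 0),
                   list(p0 = fb$anchor, p1 = fb$anchor + u2 * L / 2, s0 = L / 2))
      kink_xy <- rbind(kink_xy, fb$anchor)
    } else {
      segs <- list(list(p0 = fb$anchor - u * L / 2,
                        p1 = fb$anchor + u * L / 2, s0 = 0))
    }
    contrib <- rep(0, n_px * n_px)
    for (sg in segs) {
      r <- seg_render(px, py, sg$p0, sg$p1, sg$s0)
      inside <- r$dist < half_w
      if (!any(inside)) next
      prof <- sqrt(pmax(0, 1 - (r$dist[inside] / half_w)^2))
      band <- 1 - depth * 0.5 * (1 + cos(2 * pi * (r$s[inside] + fb$band_phase) / P))
      contrib[inside] <- pmax(contrib[inside], H * prof * band)
    }
    heights <- pmax(heights, matrix(contrib, n_px, n_px))
  }

  if (config$blur_sigma_nm > 0) {
    heights <- gaussian_blur(heights, config$blur_sigma_nm / px_nm)
  }
  if (config$noise_sigma_nm > 0) {
    noise <- local_seed(config$seed + 1L,
                        stats::rnorm(n_px * n_px, 0, config$noise_sigma_nm))
    heights <- heights + matrix(noise, n_px, n_px)
  }

  image <- as_afm_image(heights, px_size_nm = px_nm,
                        id = sprintf("phantom-img-seed%d", config$seed))

  # ground-truth labels per ROI, from geometry only
  roi_px <- cst$roi_px
  n_roi <- n_px %/% roi_px
  clarity <- as.integer(config$blur_sigma_nm <= cst$clarity_blur_max_nm &&
                          config$noise_sigma_nm <= cst$clarity_noise_max_nm)
  dbanding <- as.integer(depth >= cst$dband_depth_min &&
                           config$blur_sigma_nm <= cst$dband_blur_max_nm)
  random_orient <- as.integer(config$orientation_mode == "random")

  grid <- expand.grid(roi_col = seq_len(n_roi) - 1L,
                      roi_row = seq_len(n_roi) - 1L)[, 2:1]
  roi_nm <- roi_px * px_nm
  linearity <- rep(1L, nrow(grid))
  if (nrow(kink_xy) > 0) {
    for (k in seq_len(nrow(kink_xy))) {
      cc <- floor(kink_xy[k, 1] / roi_nm)   # x -> column
      rr <- floor(kink_xy[k, 2] / roi_nm)   # y -> row
      hit <- grid$roi_row == rr & grid$roi_col == cc
      linearity[hit] <- 0L
    }
  }
  # fibril coverage per ROI, from the polyline geometry (not pixels):
  # an ROI is covered when any fibril centerline passes within half a
  # fibril width of its extent
  cov_count <- matrix(0L, n_roi, n_roi)
  mark_cover <- function(mat, p0, p1) {
    L_seg <- sqrt(sum((p1 - p0)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(L_seg / 25)))
    for (tt in ts) {
      q <- p0 + tt * (p1 - p0)
      cols <- floor((q[1] + c(-half_w, half_w)) / roi_nm)
      rows <- floor((q[2] + c(-half_w, half_w)) / roi_nm)
      cols <- pmin(pmax(cols, 0), n_roi - 1L)
      rows <- pmin(pmax(rows, 0), n_roi - 1L)
      if (q[1] > -half_w && q[1] < field_nm + half_w &&
          q[2] > -half_w && q[2] < field_nm + half_w) {
        mat[(rows[1]:rows[2]) + 1L, (cols[1]:cols[2]) + 1L] <- TRUE
      }
    }
    mat
  }
  for (fb in fibrils) {
    u <- c(cos(fb$phi), sin(fb$phi))
    this_cov <- matrix(FALSE, n_roi, n_roi)
    if (fb$kinked) {
      u2 <- c(cos(fb$phi + fb$dphi), sin(fb$phi + fb$dphi))
      this_cov <- mark_cover(this_cov, fb$anchor - u * L / 2, fb$anchor)
      this_cov <- mark_cover(this_cov, fb$anchor, fb$anchor + u2 * L / 2)
    } else {
      this_cov <- mark_cover(this_cov, fb$anchor - u * L / 2,
                             fb$anchor + u * L / 2)
    }
    cov_count <- cov_count + this_cov
  }
  n_cover <- cov_count[cbind(grid$roi_row + 1L, grid$roi_col + 1L)]
  labels <- data.frame(roi_row = grid$roi_row, roi_col = grid$roi_col,
                       clarity = clarity, dbanding = dbanding,
                       random_orientation = random_orient,
                       linearity = linearity,
                       covered = as.integer(n_cover >= 1L),
                       n_cover = as.integer(n_cover))
  attr(labels, "kink_xy_nm") <- kink_xy
  list(image = image, labels = labels)
}
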