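#' Clean phantom class sets for classifier evaluation
#'
#' Builds a balanced two-class feature/label set for one morphometry
#' metric from phantom images whose generating parameters sit far on
#' either side of the ground-truth label cutoffs, restricted to ROIs
#' where the metric is locally decidable:
#' \describe{
#'   \item{dbanding}{full banding depth (0.35) vs none (0); fibril-covered
#'     ROIs only (bare substrate carries no banding information).}
#'   \item{clarity}{no blur/low noise vs heavy blur (45 nm) and noise;
#'     covered ROIs only.}
#'   \item{random_orientation}{dense random vs dense aligned scans
#'     (22 fibrils); ROIs crossed by >= 3 fibrils, since a single fibril
#'     is always locally "aligned" and cannot reveal scan isotropy.}
#'   \item{linearity}{ROIs holding a kink vertex in their central region
#'     (>= 250 nm from every ROI edge, so both arms are visible) vs ROIs
#'     traversed by exactly one straight fibril (crossings of distinct
#'     straight fibrils locally mimic kinks and are excluded from the
#'     clean class).}
#' }
#' All restrictions are computed from the generator geometry, never from
#' pixels. Images are generated (6 or 10 um fields) until both classes
#' reach `n_per_class` ROIs.
#'
#' @param metric one of `"dbanding"`, `"clarity"`, `"random_orientation"`,
#'   `"linearity"`.
#' @param n_per_class target ROIs per class (default 100).
#' @param seed integer seed; image seeds derive from it.
#' @return list with `features` (matrix), `labels` (0/1 vector) and
#'   `n_images` used.
#' @export
clean_class_rois <- function(metric = c("dbanding", "clarity",
                                        "random_orientation", "linearity"),
                             n_per_class = 100, seed = 1L) {
  metric <- match.arg(metric)
  seed <- as.integer(seed)

  grab <- function(cfg) {
    g <- generate_fibril_image(cfg)
    X <- feature_matrix(lapply(patch_image(g$image), extract_features))
    list(X = X, lab = g$labels, kink_xy = attr(g$labels, "kink_xy_nm"))
  }

  # ROIs holding a kink vertex at least `margin` nm inside their extent
  central_kink_sel <- function(lab, kink_xy, roi_nm = 1000, margin = 250) {
    sel <- rep(FALSE, nrow(lab))
    if (is.null(kink_xy) || nrow(kink_xy) == 0) return(sel)
    n_roi <- max(lab$roi_row) + 1L
    for (j in seq_len(nrow(kink_xy))) {
      cc <- floor(kink_xy[j, 1] / roi_nm)
      rr <- floor(kink_xy[j, 2] / roi_nm)
      if (rr < 0 || cc < 0 || rr >= n_roi || cc >= n_roi) next
      dx <- min(kink_xy[j, 1] - cc * roi_nm, (cc + 1) * roi_nm - kink_xy[j, 1])
      dy <- min(kink_xy[j, 2] - rr * roi_nm, (rr + 1) * roi_nm - kink_xy[j, 2])
      if (min(dx, dy) > margin) sel[lab$roi_row == rr & lab$roi_col == cc] <- TRUE
    }
    sel
  }

  # accumulate class ROIs image by image until both classes are filled
  pos <- list(); neg <- list(); n_pos <- 0L; n_neg <- 0L; img <- 0L
  max_img <- 200L
  while ((n_pos < n_per_class || n_neg < n_per_class) && img < max_img) {
    img <- img + 1L
    s <- seed + 1000L * img
    cl <- switch(metric,
      dbanding = {
        if (n_pos <= n_neg) {
          g <- grab(phantom_image_config(dband_depth = 0.35, seed = s))
          list(side = "pos", keep = g$lab$covered == 1, g = g)
        } else {
          g <- grab(phantom_image_config(dband_depth = 0, seed = s))
          list(side = "neg", keep = g$lab$covered == 1, g = g)
        }
      },
      clarity = {
        if (n_pos <= n_neg) {
          g <- grab(phantom_image_config(seed = s))
          list(side = "pos", keep = g$lab$covered == 1, g = g)
        } else {
          g <- grab(phantom_image_config(blur_sigma_nm = 45,
                                         noise_sigma_nm = 3, seed = s))
          list(side = "neg", keep = g$lab$covered == 1, g = g)
        }
      },
      random_orientation = {
        if (n_pos <= n_neg) {
          g <- grab(phantom_image_config(n_fibrils = 22, seed = s))
          list(side = "pos", keep = g$lab$n_cover >= 3, g = g)
        } else {
          g <- grab(phantom_image_config(n_fibrils = 22,
                                         orientation_mode = "aligned",
                                         aligned_axis_deg = 30, seed = s))
          list(side = "neg", keep = g$lab$n_cover >= 3, g = g)
        }
      },
      linearity = {
        if (n_neg <= n_pos) {   # negatives (kinked) are the scarce class
          g <- grab(phantom_image_config(field_size_um = 6, kink_prob = 1,
                                         n_fibrils = 8, seed = s))
          list(side = "neg",
               keep = g$lab$linearity == 0 &
                      central_kink_sel(g$lab, g$kink_xy), g = g)
        } else {
          g <- grab(phantom_image_config(field_size_um = 6, n_fibrils = 4,
                                         seed = s))
          list(side = "pos", keep = g$lab$n_cover == 1, g = g)
        }
      })
    X <- cl$g$X[cl$keep, , drop = FALSE]
    if (nrow(X) == 0) next
    if (cl$side == "pos" && n_pos < n_per_class) {
      take <- min(nrow(X), n_per_class - n_pos)
      pos[[length(pos) + 1L]] <- X[seq_len(take), , drop = FALSE]
      n_pos <- n_pos + take
    } else if (cl$side == "neg" && n_neg < n_per_class) {
      take <- min(nrow(X), n_per_class - n_neg)
      neg[[length(neg) + 1L]] <- X[seq_len(take), , drop = FALSE]
      n_neg <- n_neg + take
    }
  }
  Xp <- do.call(rbind, pos); Xn <- do.call(rbind, neg)
  list(features = rbind(Xp, Xn),
       labels = c(rep(1L, nrow(Xp)), rep(0L, nrow(Xn))),
       n_images = img)
}
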