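# lower convex hull (Andrew monotone chain) over points sorted by x;
# returns indices of the hull vertices
lower_hull_idx <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      # drop b if it lies above the line a-i (not convex downward)
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  hull
}

#' Baseline-correct and normalize an FTIR spectrum
#'
#' Rubber-band baseline correction: the lower convex hull of the spectrum
#' is interpolated and subtracted (a linear-baseline fallback, anchored at
#' the range endpoints, is available behind `method = "linear"`), after
#' which the spectrum is normalized to unit Amide I peak height (maximum
#' in 1580-1720 cm^-1). Adding any affine baseline to the input leaves the
#' rubber-band output unchanged, and the operation is idempotent.
#'
#' @param spectrum a `ftir_spectrum` covering at least 800-1800 cm^-1.
#' @param method `"rubberband"` (default) or `"linear"`.
#' @return The preprocessed `ftir_spectrum`; both steps are appended to
#'   `preprocessing_log`.
#' @export
preprocess_spectrum <- function(spectrum, method = c("rubberband", "linear")) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  method <- match.arg(method)
  w <- spectrum$wavenumbers_cm1
  a <- spectrum$absorbance
  if (min(w) > 800 || max(w) < 1800) {
    stopf("spectrum must cover at least 800-1800 cm^-1")
  }
  if (method == "rubberband") {
    hi <- lower_hull_idx(w, a)
    base <- stats::approx(w[hi], a[hi], xout = w, rule = 2)$y
  } else {
    base <- a[1] + (a[length(a)] - a[1]) / (w[length(w)] - w[1]) * (w - w[1])
  }
  corrected <- a - base
  amide_I_win <- w >= 1580 & w <= 1720
  peak <- max(corrected[amide_I_win])
  if (peak <= 0) stopf("no Amide I intensity after baseline correction")
  as_ftir_spectrum(w, corrected / peak, id = spectrum$id,
                   preprocessing_log = c(spectrum$preprocessing_log,
                                         paste0("baseline:", method),
                                         "normalize:amideI_unit_peak"))
}

# Savitzky-Golay-style quadratic smoothing with a fixed odd window
sg_smooth <- function(y, window = collafib_constants$sg_window_pts) {
  half <- (window - 1L) %/% 2L
  x <- seq(-half, half)
  X <- cbind(1, x, x^2)
  # convolution weights for the fitted value at the window center
  wts <- (solve(crossprod(X)) %*% t(X))[1, ]
  n <- length(y)
  pad <- c(rev(y[seq_len(half) + 1L]), y, rev(y[n - seq_len(half)]))
  out <- numeric(n)
  for (j in seq_len(window)) out <- out + wts[j] * pad[seq_len(n) + j - 1L]
  out
}

# local maxima indices of a smoothed trace above a height floor
find_peaks <- function(y, min_height) {
  n <- length(y)
  if (n < 3) return(integer(0))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  idx[y[idx] >= min_height]
}

#' Amide-band metrics of a preprocessed collagen spectrum
#'
#' Peak detection on a Savitzky-Golay-smoothed trace inside documented
#' windows: Amide I in 1600-1700 cm^-1, Amide II in 1500-1590 cm^-1, and
#' the Amide III triplet in +/-10 cm^-1 sub-windows around 1205, 1235 and
#' 1280 cm^-1. The I/II ratio is the ratio of baseline-corrected peak
#' heights (integrated-area mode behind `ratio_mode = "area"`). The
#' denaturation signature is `Amide I peak >= 1637 cm^-1 AND triplet
#' absent`.
#'
#' @param spectrum a preprocessed `ftir_spectrum` (see
#'   [preprocess_spectrum()]; applied automatically if the log is empty).
#' @param ratio_mode `"height"` (default) or `"area"`.
#' @param min_peak_height minimum normalized height for a detected peak
#'   (default `collafib_constants$peak_min_height`).
#' @return A `band_metrics` list: `amideI_peak_cm1`, `amideII_peak_cm1`,
#'   `amideI_II_ratio`, `amideIII_triplet_present`,
#'   `amideIII_positions_cm1`, `denatured_signature`.
#' @examples
#' s <- generate_ftir_spectrum(spectrum_config("native"))
#' band_metrics(preprocess_spectrum(s))$amideIII_triplet_present
#' @export
band_metrics <- function(spectrum, ratio_mode = c("height", "area"),
                         min_peak_height = collafib_constants$peak_min_height) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  ratio_mode <- match.arg(ratio_mode)
  if (length(spectrum$preprocessing_log) == 0) {
    spectrum <- preprocess_spectrum(spectrum)
  }
  w <- spectrum$wavenumbers_cm1
  a <- spectrum$absorbance
  s <- sg_smooth(a)

  peak_in <- function(lo, hi) {
    win <- which(w >= lo & w <= hi)
    if (length(win) < 3) return(NULL)
    pk <- find_peaks(s[win], min_peak_height)
    if (length(pk) == 0) return(NULL)
    best <- pk[which.max(s[win][pk])]
    i <- win[best]
    list(cm1 = w[i], height = a[i],
         area = sum(a[win][a[win] > 0]) * mean(diff(w[win])))
  }

  amideI <- peak_in(1600, 1700)
  if (is.null(amideI)) stopf("no Amide I peak found: not a collagen-like spectrum")
  amideII <- peak_in(1500, 1590)

  triplet_centers <- c(1205, 1235, 1280)
  subs <- lapply(triplet_centers, function(cc) peak_in(cc - 10, cc + 10))
  triplet <- all(!vapply(subs, is.null, logical(1)))
  positions <- vapply(subs, function(p) if (is.null(p)) NA_real_ else p$cm1,
                      numeric(1))

  ratio <- NA_real_
  if (!is.null(amideII)) {
    ratio <- if (ratio_mode == "height") amideI$height / amideII$height
             else amideI$area / amideII$area
  }
  structure(
    list(amideI_peak_cm1 = amideI$cm1,
         amideII_peak_cm1 = if (is.null(amideII)) NA_real_ else amideII$cm1,
         amideI_II_ratio = ratio,
         amideIII_triplet_present = triplet,
         amideIII_positions_cm1 = positions,
         denatured_signature = (amideI$cm1 >= 1637) && !triplet,
         ratio_mode = ratio_mode),
    class = "band_metrics"
  )
}

#' Compare Amide I/II ratios between two groups
#'
#' Difference of group means plus a two-sided Mann-Whitney rank-sum test
#' (see [rank_sum_test()]).
#'
#' @param ratios_a,ratios_b numeric vectors of Amide I/II ratios
#'   (>= 3 each).
#' @return list with `diff_means`, `U`, `p_value`, group sizes.
#' @export
compare_ratios <- function(ratios_a, ratios_b) {
  if (length(ratios_a) < 3 || length(ratios_b) < 3) {
    stopf("need >= 3 spectra per group")
  }
  rs <- rank_sum_test(ratios_a, ratios_b)
  list(diff_means = mean(ratios_a) - mean(ratios_b),
       U = rs$U, p_value = rs$p_value, n_a = rs$n_a, n_b = rs$n_b)
}
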