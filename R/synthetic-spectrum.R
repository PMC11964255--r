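#' Default amide band table for a collagen-like spectrum
#'
#' Gaussian components (center, sigma in cm^-1, amplitude relative to
#' Amide I) for the native and thermally denatured states. The native
#' state carries Amide A (~3300), Amide I (~1630), Amide II (~1540), a CH
#' bending band (~1450) and the Amide III triplet (~1205/1235/1280).
#' Denaturation shifts Amide I to ~1640, reduces Amide II, and removes
#' the triplet entirely.
#'
#' @param state `"native"` or `"denatured"`.
#' @param amideI_amideII_ratio configured Amide I : Amide II amplitude
#'   ratio for the native state (default 1.6).
#' @return data.frame with columns `name`, `center_cm1`, `sigma_cm1`,
#'   `amplitude`.
#' @export
collagen_bands <- function(state = c("native", "denatured"),
                           amideI_amideII_ratio = 1.6) {
  state <- match.arg(state)
  check_number(amideI_amideII_ratio, "amideI_amideII_ratio", positive = TRUE)
  if (state == "native") {
    data.frame(
      name = c("amideA", "amideI", "amideII", "CH_bend",
               "amideIII_1205", "amideIII_1235", "amideIII_1280"),
      center_cm1 = c(3300, 1630, 1540, 1450, 1205, 1235, 1280),
      sigma_cm1 = c(90, 25, 22, 18, 9, 9, 9),
      amplitude = c(0.55, 1.0, 1.0 / amideI_amideII_ratio, 0.20,
                    0.13, 0.18, 0.15),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      name = c("amideA", "amideI", "amideII", "CH_bend"),
      center_cm1 = c(3300, 1641, 1540, 1450),
      sigma_cm1 = c(95, 30, 24, 18),
      amplitude = c(0.50, 1.0, 0.30, 0.18),
      stringsAsFactors = FALSE
    )
  }
}

#' Configuration for a synthetic ATR-FTIR collagen spectrum
#'
#' @param state `"native"` or `"denatured"`.
#' @param bands band table as from [collagen_bands()]; defaults to the
#'   state's canonical table.
#' @param baseline_slope linear baseline slope (absorbance per cm^-1).
#' @param noise_sd additive Gaussian noise SD (absorbance units).
#' @param wavenumber_step grid step in cm^-1 (default 2, i.e. 4 cm^-1
#'   resolution spectra).
#' @param seed integer seed.
#' @return A `spectrum_config` list.
#' @export
spectrum_config <- function(state = c("native", "denatured"),
                            bands = NULL, baseline_slope = 0,
                            noise_sd = 0, wavenumber_step = 2, seed = 1L) {
  state <- match.arg(state)
  if (is.null(bands)) bands <- collagen_bands(state)
  stopifnot(is.data.frame(bands),
            all(c("name", "center_cm1", "sigma_cm1", "amplitude") %in% names(bands)))
  if (any(bands$center_cm1 < 800) || any(bands$center_cm1 > 4000)) {
    stopf("band center outside the 800-4000 cm^-1 range")
  }
  if (any(bands$sigma_cm1 <= 0) || any(bands$amplitude < 0)) {
    stopf("band widths must be > 0 and amplitudes >= 0")
  }
  check_number(baseline_slope, "baseline_slope")
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  structure(
    list(state = state, bands = bands, baseline_slope = baseline_slope,
         noise_sd = noise_sd, wavenumber_step = wavenumber_step,
         seed = as.integer(seed)),
    class = "spectrum_config"
  )
}

#' Generate a synthetic collagen-like FTIR spectrum
#'
#' Sum of Gaussian bands over 800-4000 cm^-1 plus a linear baseline and
#' optional noise.
#'
#' @param config a [spectrum_config()].
#' @return A `ftir_spectrum` (see [as_ftir_spectrum()]).
#' @examples
#' s <- generate_ftir_spectrum(spectrum_config("native"))
#' @export
generate_ftir_spectrum <- function(config) {
  stopifnot(inherits(config, "spectrum_config"))
  w <- seq(800, 4000, by = config$wavenumber_step)
  a <- numeric(length(w))
  for (i in seq_len(nrow(config$bands))) {
    b <- config$bands[i, ]
    a <- a + b$amplitude * exp(-0.5 * ((w - b$center_cm1) / b$sigma_cm1)^2)
  }
  a <- a + config$baseline_slope * (w - 800)
  if (config$noise_sd > 0) {
    a <- a + local_seed(config$seed, stats::rnorm(length(w), 0, config$noise_sd))
  }
  s <- as_ftir_spectrum(w, a, id = sprintf("phantom-%s-seed%d",
                                           config$state, config$seed))
  attr(s, "truth") <- list(state = config$state, bands = config$bands)
  s
}

#' Construct an FTIR spectrum object
#'
#' @param wavenumbers_cm1 strictly ascending wavenumber grid.
#' @param absorbance matched absorbance values.
#' @param id identifier.
#' @param preprocessing_log character vector of applied steps.
#' @return A `ftir_spectrum` list.
#' @export
as_ftir_spectrum <- function(wavenumbers_cm1, absorbance, id = "",
                             preprocessing_log = character()) {
  if (length(wavenumbers_cm1) != length(absorbance)) {
    stopf("wavenumbers and absorbance must have equal length")
  }
  if (any(diff(wavenumbers_cm1) <= 0)) {
    stopf("wavenumbers must be strictly ascending")
  }
  if (any(!is.finite(absorbance))) stopf("absorbance contains non-finite values")
  structure(
    list(wavenumbers_cm1 = as.numeric(wavenumbers_cm1),
         absorbance = as.numeric(absorbance),
         id = id, preprocessing_log = preprocessing_log),
    class = "ftir_spectrum"
  )
}
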