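#' Physical and pipeline constants
#'
#' Named constants used across the package, pinned in one place so every
#' module (and every test) agrees on them.
#'
#' Physical constants are deliberately stored at the rounding used in the
#' irradiation-source arithmetic (elementary charge 1.602e-19 C), so that
#' e.g. a 100 keV photon carries exactly 1.602e-14 J.
#'
#' Phantom label cutoffs define where the synthetic-image generator places
#' the ground-truth morphometry labels; they are generator conventions, not
#' measured quantities. A region of interest (ROI) is labelled:
#' \itemize{
#'   \item D-banding present when the configured banding depth is at least
#'     `dband_depth_min` and the degradation blur is at most
#'     `dband_blur_max_nm`;
#'   \item clear when blur is at most `clarity_blur_max_nm` and additive
#'     height noise at most `clarity_noise_max_nm`;
#'   \item randomly oriented when the generator's orientation mode is
#'     `"random"`;
#'   \item linear when no fibril kink vertex falls inside the ROI.
#' }
#'
#' @format A named list.
#' @export
collafib_constants <- list(
  # physics (rounded as in the dosimetry arithmetic)
  electron_charge_C   = 1.602e-19,
  planck_J_s          = 6.626e-34,
  light_speed_m_s     = 2.998e8,

  # canonical collagen axial repeat
  dband_period_nm     = 67,

  # AFM scan geometry: 10 um field sampled at 51 px/um -> 510 px,
  # patched into 51 px (1 um) ROIs
  roi_px              = 51,
  px_per_um_default   = 51,

  # phantom ground-truth label cutoffs (generator conventions)
  dband_depth_min     = 0.10,
  dband_blur_max_nm   = 30,
  clarity_blur_max_nm = 30,
  clarity_noise_max_nm = 2.0,

  # LDA ridge added to the pooled covariance diagonal (fraction of the
  # mean diagonal element)
  lda_ridge           = 1e-4,

  # contact-point detection: baseline mean + k * baseline SD
  contact_k_sd        = 3,

  # FTIR peak detection
  sg_window_pts       = 9,     # Savitzky-Golay-style smoothing window
  peak_min_height     = 0.02   # minimum normalized height for a real peak
)
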