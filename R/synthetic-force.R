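#' Configuration for a synthetic Hertzian force curve
#'
#' Forward model of an AFM indentation on a stiff fibril with a quadratic
#' pyramid tip: zero-mean baseline before contact, then
#' `F(delta) = (tan(theta)/sqrt(2)) * (E/(1-nu^2)) * delta^2`,
#' truncated at the maximum load. With E in GPa, delta in nm, F is in nN
#' (1 GPa = 1 nN/nm^2).
#'
#' @param E_true_GPa ground-truth indentation modulus (> 0).
#' @param poisson_ratio Poisson ratio nu (default 0.5, incompressible).
#' @param half_angle_deg pyramid half angle to face (default 20.8).
#' @param max_load_nN load cap in nN (default 100, the protocol cap).
#' @param n_points number of samples along the curve.
#' @param force_noise_nN additive Gaussian force noise SD (nN).
#' @param contact_offset_nm pre-contact baseline length (nm); the contact
#'   point sits at this tip displacement.
#' @param seed integer seed; same config + seed is bit-identical.
#' @return A `force_curve_config` list.
#' @export
force_curve_config <- function(E_true_GPa,
                               poisson_ratio = 0.5,
                               half_angle_deg = 20.8,
                               max_load_nN = 100,
                               n_points = 400,
                               force_noise_nN = 0,
                               contact_offset_nm = 25,
                               seed = 1L) {
  check_number(E_true_GPa, "E_true_GPa", positive = TRUE)
  check_number(poisson_ratio, "poisson_ratio")
  if (half_angle_deg <= 0 || half_angle_deg >= 90) {
    stopf("`half_angle_deg` must be in (0, 90)")
  }
  check_number(max_load_nN, "max_load_nN", positive = TRUE)
  if (max_load_nN > 100) {
    warning("max_load_nN exceeds the 100 nN protocol cap", call. = FALSE)
  }
  check_number(n_points, "n_points", positive = TRUE)
  if (n_points < 20) stopf("`n_points` must be >= 20")
  check_number(force_noise_nN, "force_noise_nN", nonneg = TRUE)
  check_number(contact_offset_nm, "contact_offset_nm", positive = TRUE)
  structure(
    list(E_true_GPa = E_true_GPa, poisson_ratio = poisson_ratio,
         half_angle_deg = half_angle_deg, max_load_nN = max_load_nN,
         n_points = as.integer(n_points), force_noise_nN = force_noise_nN,
         contact_offset_nm = contact_offset_nm, seed = as.integer(seed)),
    class = "force_curve_config"
  )
}

#' Hertz pyramid prefactor
#'
#' `tan(theta)/sqrt(2)` ("sqrt2", quadratic-pyramid convention) or
#' `0.7453 * tan(theta)` ("bilodeau"); the two differ by ~5%.
#'
#' @param half_angle_deg pyramid half angle to face, degrees.
#' @param prefactor which convention to use.
#' @return Dimensionless prefactor multiplying `E/(1-nu^2) * delta^2`.
#' @export
hertz_prefactor <- function(half_angle_deg, prefactor = c("sqrt2", "bilodeau")) {
  prefactor <- match.arg(prefactor)
  th <- tan(half_angle_deg * pi / 180)
  switch(prefactor, sqrt2 = th / sqrt(2), bilodeau = 0.7453 * th)
}

#' Generate a synthetic force-distance curve
#'
#' Tip displacement (`distance_nm`) increases from 0 toward the sample;
#' force is zero-mean noise before the contact point and follows the
#' Hertzian pyramid law after it, up to the configured load cap.
#' Ground truth (modulus, contact point, maximum depth) is attached as the
#' `"truth"` attribute for round-trip testing.
#'
#' @param config a [force_curve_config()].
#' @return A `force_curve` object (see [as_force_curve()]).
#' @examples
#' fc <- generate_force_curve(force_curve_config(4.82, seed = 7))
#' attr(fc, "truth")$max_depth_nm  # closed-form depth at 100 nN
#' @export
generate_force_curve <- function(config) {
  stopifnot(inherits(config, "force_curve_config"))
  C <- hertz_prefactor(config$half_angle_deg) / (1 - config$poisson_ratio^2)
  depth_max <- sqrt(config$max_load_nN / (C * config$E_true_GPa))
  zc <- config$contact_offset_nm
  z <- seq(0, zc + depth_max, length.out = config$n_points)
  delta <- pmax(0, z - zc)
  f_model <- C * config$E_true_GPa * delta^2
  noise <- if (config$force_noise_nN > 0) {
    local_seed(config$seed, rnorm(length(z), 0, config$force_noise_nN))
  } else rep(0, length(z))
  curve <- as_force_curve(distance_nm = z, force_nN = f_model + noise,
                          direction = "extend",
                          spring_constant_N_per_m = 2.8,
                          id = sprintf("phantom-E%.3g-seed%d",
                                       config$E_true_GPa, config$seed))
  attr(curve, "truth") <- list(E_GPa = config$E_true_GPa,
                               contact_point_nm = zc,
                               max_depth_nm = depth_max,
                               prefactor_x_modulus = C * config$E_true_GPa)
  curve
}

#' Construct a force-curve object
#'
#' @param distance_nm monotone tip displacement samples (nm), baseline first.
#' @param force_nN matched force samples (nN).
#' @param direction `"extend"` or `"retract"`.
#' @param spring_constant_N_per_m cantilever spring constant metadata.
#' @param id free-text identifier.
#' @return A `force_curve` list.
#' @export
as_force_curve <- function(distance_nm, force_nN, direction = "extend",
                           spring_constant_N_per_m = 2.8, id = "") {
  if (length(distance_nm) != length(force_nN)) {
    stopf("distance and force must have equal length")
  }
  if (length(distance_nm) < 20) stopf("force curve needs >= 20 samples")
  if (any(!is.finite(distance_nm)) || any(!is.finite(force_nN))) {
    stopf("force curve contains non-finite values")
  }
  d <- diff(distance_nm)
  if (!(all(d >= 0) || all(d <= 0))) stopf("`distance_nm` must be monotone")
  if (max(abs(force_nN)) > 1000) stopf("|force| exceeds 1000 nN sanity bound")
  direction <- match.arg(direction, c("extend", "retract"))
  structure(
    list(distance_nm = as.numeric(distance_nm),
         force_nN = as.numeric(force_nN),
         direction = direction,
         spring_constant_N_per_m = spring_constant_N_per_m,
         id = id),
    class = "force_curve"
  )
}
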