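#' Detect the contact point of a force curve
#'
#' Baseline statistics (mean, SD) are taken from the leading pre-contact
#' segment of the curve; the contact point is the displacement at which the
#' force first exceeds `baseline mean + k * baseline SD` and stays above it
#' for the following sample. The rule is baseline-relative, so a constant
#' force offset leaves the detected contact unchanged. [fit_hertz_pyramid()]
#' subsequently refines the contact point as a free fit parameter.
#'
#' @param curve a `force_curve`.
#' @param k threshold multiplier on the baseline SD (default
#'   `collafib_constants$contact_k_sd` = 3).
#' @param baseline_frac fraction of leading samples assumed pre-contact for
#'   the baseline statistics (default 0.2, at least 10 samples).
#' @return Contact point in nm (same axis as `distance_nm`).
#' @export
find_contact_point <- function(curve, k = collafib_constants$contact_k_sd,
                               baseline_frac = 0.2) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$distance_nm
  f <- curve$force_nN
  n <- length(f)
  n0 <- max(10L, floor(baseline_frac * n))
  base <- f[seq_len(n0)]
  thr <- mean(base) + k * stats::sd(base)
  above <- f > thr
  # require two consecutive samples above threshold (noise robustness)
  idx <- which(above & c(above[-1], FALSE))
  if (length(idx) == 0) stopf("no contact detected")
  z[idx[1]]
}

#' Fit the Hertzian quadratic-pyramid model to a force curve
#'
#' Least-squares fit of `F(delta) = prefactor * (E/(1-nu^2)) * delta^2`,
#' with `delta = max(0, z - z_c)`, over the extend segment. The contact
#' point `z_c` and the modulus `E` are both free: for any candidate `z_c`
#' the modulus has the closed-form weighted solution
#' `E = sum(F delta^2) / (C sum(delta^4))`, and `z_c` is optimized by a
#' bounded 1-D search around the threshold-detected contact. If no baseline
#' rise is detectable the fit falls back to scanning `z_c` over the whole
#' curve (`contact_fallback` flag in the result).
#'
#' @param curve a `force_curve` (extend segment).
#' @param nu Poisson ratio (default 0.5; the protocol does not state one).
#' @param half_angle_deg pyramid half angle to face (default 20.8).
#' @param prefactor `"sqrt2"` (tan(theta)/sqrt 2) or `"bilodeau"`
#'   (0.7453 tan(theta)); see [hertz_prefactor()].
#' @return A `hertz_fit` object: `E_GPa`, `contact_point_nm`,
#'   `max_depth_nm`, `poisson_ratio`, `half_angle_deg`, `rms_residual_nN`,
#'   `converged`, `contact_fallback`, `n_post_contact`.
#' @examples
#' fc <- generate_force_curve(force_curve_config(4.82))
#' fit_hertz_pyramid(fc)$E_GPa
#' @export
fit_hertz_pyramid <- function(curve, nu = 0.5, half_angle_deg = 20.8,
                              prefactor = c("sqrt2", "bilodeau")) {
  stopifnot(inherits(curve, "force_curve"))
  prefactor <- match.arg(prefactor)
  if (curve$direction != "extend") {
    warning("fitting a non-extend segment; the model assumes extend", call. = FALSE)
  }
  z <- curve$distance_nm
  f <- curve$force_nN
  C <- hertz_prefactor(half_angle_deg, prefactor) / (1 - nu^2)

  zc0 <- tryCatch(find_contact_point(curve), error = function(e) NA_real_)
  fallback <- is.na(zc0)
  dz <- stats::median(abs(diff(z)))
  span <- max(z) - min(z)
  if (fallback) {
    lower <- min(z)
    upper <- max(z) - 10 * dz
  } else {
    # threshold detection always fires after true contact, so search a
    # generous window extending well before the detected point
    lower <- max(min(z), zc0 - 0.3 * span)
    upper <- min(max(z) - 10 * dz, zc0 + 10 * dz)
  }

  e_for_zc <- function(zc) {
    delta <- pmax(0, z - zc)
    s4 <- sum(delta^4)
    if (s4 == 0) return(list(E = NA_real_, ssr = Inf, delta = delta))
    E <- sum(f * delta^2) / (C * s4)
    r <- f - C * E * delta^2
    list(E = E, ssr = sum(r^2), delta = delta)
  }
  obj <- function(zc) e_for_zc(zc)$ssr
  # coarse scan then local refinement (SSR need not be unimodal in noise)
  cand <- seq(lower, upper, length.out = 64)
  ssr <- vapply(cand, obj, numeric(1))
  i_best <- which.min(ssr)
  step <- cand[2] - cand[1]
  opt <- stats::optimize(obj, lower = max(lower, cand[i_best] - step),
                         upper = min(upper, cand[i_best] + step), tol = 1e-8)
  sol <- e_for_zc(opt$minimum)
  n_post <- sum(sol$delta > 0)
  converged <- is.finite(sol$E) && sol$E > 0 && n_post >= 10
  structure(
    list(E_GPa = sol$E,
         contact_point_nm = opt$minimum,
         max_depth_nm = max(sol$delta),
         poisson_ratio = nu,
         half_angle_deg = half_angle_deg,
         prefactor = prefactor,
         rms_residual_nN = sqrt(sol$ssr / length(f)),
         converged = converged,
         contact_fallback = fallback,
         n_post_contact = n_post,
         id = curve$id),
    class = "hertz_fit"
  )
}

#' Summarize a group of Hertz fits
#'
#' Median indentation modulus over converged fits, median absolute
#' deviation, and (when a paired control is given) the percent variation
#' `100 * (median_group - median_control) / median_control` computed from
#' unrounded medians, plus a Mann-Whitney comparison against the control's
#' moduli.
#'
#' @param fits list of `hertz_fit` objects (or a numeric vector of moduli).
#' @param paired_control optional `group_summary` of the paired control.
#' @param group_id identifier for the group.
#' @return A `group_summary`: `group_id`, `n`, `median_GPa`,
#'   `median_abs_dev_GPa`, `variation_pct`, `p_value`, `significant`,
#'   and the underlying `moduli`.
#' @export
summarize_group <- function(fits, paired_control = NULL, group_id = "") {
  moduli <- if (is.numeric(fits)) fits else {
    vapply(fits, function(f) {
      stopifnot(inherits(f, "hertz_fit"))
      if (isTRUE(f$converged)) f$E_GPa else NA_real_
    }, numeric(1))
  }
  moduli <- moduli[is.finite(moduli)]
  if (length(moduli) == 0) stopf("no converged fits in group '%s'", group_id)
  med <- stats::median(moduli)
  variation <- NA_real_
  p <- NA_real_
  if (!is.null(paired_control)) {
    stopifnot(inherits(paired_control, "group_summary"))
    variation <- 100 * (med - paired_control$median_GPa) / paired_control$median_GPa
    if (length(paired_control$moduli) > 0) {
      p <- rank_sum_test(moduli, paired_control$moduli)$p_value
    }
  }
  structure(
    list(group_id = group_id, n = length(moduli),
         median_GPa = med,
         median_abs_dev_GPa = stats::mad(moduli),
         variation_pct = variation,
         p_value = p,
         significant = if (is.na(p)) NA else p < 0.05,
         moduli = moduli),
    class = "group_summary"
  )
}

#' Mean and SD of a set of group medians
#'
#' Convenience summary of control-group medians (e.g. the across-control
#' average the indentation analysis reports), returned unrounded.
#'
#' @param medians numeric vector of group medians.
#' @return list with `mean`, `sd`, `n`.
#' @export
pooled_median_summary <- function(medians) {
  stopifnot(is.numeric(medians), length(medians) >= 2)
  list(mean = mean(medians), sd = stats::sd(medians), n = length(medians))
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent groups. For small samples
#' (both n <= 20) with no ties the exact null distribution is used;
#' otherwise a tie-corrected normal approximation with continuity
#' correction. `U` is reported for the first group.
#'
#' @param group_a,group_b numeric vectors.
#' @return list with `U`, `p_value`, `n_a`, `n_b`, `method`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(10, 11, 12))$p_value  # exact 0.1
#' @export
rank_sum_test <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stopf("both groups must be non-empty")
  }
  n1 <- length(group_a); n2 <- length(group_b); N <- n1 + n2
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)

  if (!has_ties && n1 <= 20 && n2 <= 20) {
    Umin <- min(U1, n1 * n2 - U1)
    p <- min(1, 2 * stats::pwilcox(Umin, n1, n2))
    method <- "exact"
  } else {
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      zval <- (U1 - n1 * n2 / 2)
      zval <- (zval - sign(zval) * 0.5) / sqrt(sigma2)  # continuity corr.
      p <- 2 * stats::pnorm(-abs(zval))
    }
    method <- "normal-approx"
  }
  list(U = U1, p_value = min(1, p), n_a = n1, n_b = n2, method = method)
}

#' Kruskal-Wallis test with Dunn's pairwise comparisons
#'
#' Tie-corrected Kruskal-Wallis H across three or more groups, followed by
#' Dunn's z tests for every pair with a multiplicity adjustment
#' (Bonferroni by default).
#'
#' @param groups list of >= 3 numeric vectors.
#' @param p_adjust adjustment method passed to [stats::p.adjust()].
#' @return list with `H`, `df`, `p_value`, and `pairs` (data frame:
#'   `group_i`, `group_j`, `z`, `p_adjusted`).
#' @export
kruskal_wallis_dunn <- function(groups, p_adjust = "bonferroni") {
  if (!is.list(groups) || length(groups) < 3) {
    stopf("need >= 3 groups; use rank_sum_test() for two")
  }
  ni <- lengths(groups)
  if (any(ni == 0)) stopf("all groups must be non-empty")
  g <- length(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  grp <- rep(seq_len(g), ni)
  rbar <- tapply(r, grp, mean)
  H <- 12 / (N * (N + 1)) * sum(ni * rbar^2) - 3 * (N + 1)
  ties <- table(pooled)
  Ccorr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (Ccorr > 0) H / Ccorr else 0
  p_overall <- stats::pchisq(H, df = g - 1, lower.tail = FALSE)

  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(g, 2)
  zs <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(base_var * (1 / ni[i] + 1 / ni[j]))
    if (se <= 0) return(0)
    (rbar[i] - rbar[j]) / se
  })
  praw <- 2 * stats::pnorm(-abs(zs))
  list(H = H, df = g - 1, p_value = p_overall,
       pairs = data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
                          z = as.numeric(zs),
                          p_adjusted = stats::p.adjust(praw, method = p_adjust)))
}
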