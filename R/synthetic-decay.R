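#' Configuration for a synthetic TCSPC decay histogram
#'
#' Tri-exponential intensity model
#' `I(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2) + a3 exp(-t/tau3)`;
#' per-bin expected counts are the analytic integral of `I` over each bin,
#' normalized so the expected total equals `n_photons`, and observed counts
#' are Poisson draws around them.
#'
#' @param amplitudes three relative amplitudes (>= 0, not all zero).
#' @param lifetimes_ns three decay times in ns (> 0).
#' @param n_photons expected total photon count.
#' @param bin_width_ps histogram bin width in ps (default 50).
#' @param window_ns collection window in ns (default 200); must be an
#'   integer number of bins.
#' @param seed integer seed.
#' @return A `decay_config` list.
#' @export
decay_config <- function(amplitudes, lifetimes_ns, n_photons = 1e6,
                         bin_width_ps = 50, window_ns = 200, seed = 1L) {
  if (length(amplitudes) != 3 || any(amplitudes < 0)) {
    stopf("`amplitudes` must be three non-negative values")
  }
  if (all(amplitudes == 0)) stopf("at least one amplitude must be > 0")
  if (length(lifetimes_ns) != 3 || any(lifetimes_ns <= 0)) {
    stopf("`lifetimes_ns` must be three positive values")
  }
  check_number(n_photons, "n_photons", positive = TRUE)
  check_number(bin_width_ps, "bin_width_ps", positive = TRUE)
  check_number(window_ns, "window_ns", positive = TRUE)
  n_bins <- window_ns * 1000 / bin_width_ps
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stopf("window_ns / bin_width_ps must give an integer bin count")
  }
  structure(
    list(amplitudes = as.numeric(amplitudes),
         lifetimes_ns = as.numeric(lifetimes_ns),
         n_photons = n_photons, bin_width_ps = bin_width_ps,
         window_ns = window_ns, seed = as.integer(seed)),
    class = "decay_config"
  )
}

# analytic per-bin integral of the tri-exponential intensity
triexp_bin_integral <- function(edges_ns, amplitudes, lifetimes_ns) {
  lo <- edges_ns[-length(edges_ns)]
  hi <- edges_ns[-1]
  out <- numeric(length(lo))
  for (j in seq_along(amplitudes)) {
    a <- amplitudes[j]; tau <- lifetimes_ns[j]
    if (a > 0) out <- out + a * tau * (exp(-lo / tau) - exp(-hi / tau))
  }
  out
}

#' Generate a synthetic TCSPC decay histogram
#'
#' @param config a [decay_config()].
#' @return A `decay_histogram` (see [as_decay_histogram()]); the exact
#'   per-bin expected counts are attached as attribute `"expected"`.
#' @examples
#' h <- generate_decay_histogram(
#'   decay_config(c(0.5, 0.3, 0.2), c(0.5, 2, 6), n_photons = 1e5, seed = 3))
#' sum(h$counts)
#' @export
generate_decay_histogram <- function(config) {
  stopifnot(inherits(config, "decay_config"))
  bw_ns <- config$bin_width_ps / 1000
  n_bins <- as.integer(round(config$window_ns / bw_ns))
  edges <- seq(0, by = bw_ns, length.out = n_bins + 1L)
  lam <- triexp_bin_integral(edges, config$amplitudes, config$lifetimes_ns)
  lam <- lam / sum(lam) * config$n_photons
  counts <- local_seed(config$seed, stats::rpois(n_bins, lam))
  h <- as_decay_histogram(bin_centers_ns = edges[-1] - bw_ns / 2,
                          counts = counts,
                          bin_width_ps = config$bin_width_ps,
                          id = sprintf("phantom-decay-seed%d", config$seed))
  attr(h, "expected") <- lam
  attr(h, "truth") <- list(amplitudes = config$amplitudes,
                           lifetimes_ns = config$lifetimes_ns,
                           avg_lifetime_ns = sum(config$amplitudes * config$lifetimes_ns) /
                             sum(config$amplitudes))
  h
}

#' Construct a decay-histogram object
#'
#' @param bin_centers_ns uniform bin centers in ns.
#' @param counts non-negative integer counts per bin.
#' @param bin_width_ps bin width in ps.
#' @param id identifier.
#' @return A `decay_histogram` list with `total_photons` filled in.
#' @export
as_decay_histogram <- function(bin_centers_ns, counts, bin_width_ps, id = "") {
  if (length(bin_centers_ns) != length(counts)) {
    stopf("bin centers and counts must have equal length")
  }
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9)) {
    stopf("counts must be non-negative integers")
  }
  d <- diff(bin_centers_ns)
  if (length(d) && (max(d) - min(d)) > 1e-6 * mean(d)) {
    stopf("bins must be uniform")
  }
  structure(
    list(bin_centers_ns = as.numeric(bin_centers_ns),
         counts = as.numeric(round(counts)),
         bin_width_ps = bin_width_ps,
         total_photons = sum(counts),
         id = id),
    class = "decay_histogram"
  )
}
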