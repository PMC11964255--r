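# Independent oracles used across the suite. These deliberately take a
# different code path from the package implementation.

# Binary LDA prediction written independently (Cholesky solve, explicit
# discriminant difference) with the same ridge convention as the package.
oracle_lda_predict <- function(Xtr, ytr, Xte,
                               ridge = collafib_constants$lda_ridge) {
  y <- as.integer(ytr)
  m0 <- colMeans(Xtr[y == 0, , drop = FALSE])
  m1 <- colMeans(Xtr[y == 1, , drop = FALSE])
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  C0 <- stats::cov(Xtr[y == 0, , drop = FALSE]) * (n0 - 1)
  C1 <- stats::cov(Xtr[y == 1, , drop = FALSE]) * (n1 - 1)
  S <- (C0 + C1) / (n0 + n1)   # MLE pooling, as in the package
  lam <- if (mean(diag(S)) > 0) ridge * mean(diag(S)) else 1e-8
  R <- chol(S + diag(lam, ncol(Xtr)))
  disc <- function(x, mu, prior) {
    z <- forwardsolve(t(R), x - mu)   # whitened residual: z'z = Mahalanobis
    -0.5 * sum(z^2) + log(prior)
  }
  apply(Xte, 1, function(x) {
    d1 <- disc(x, m1, n1 / (n0 + n1))
    d0 <- disc(x, m0, n0 / (n0 + n1))
    as.integer(d1 >= d0)   # ties toward positive, as in the package
  })
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_ranksum_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U_min <- min(U_obs, n1 * n2 - U_obs)
  combs <- utils::combn(n1 + n2, n1)
  Us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  Us_min <- pmin(Us, n1 * n2 - Us)
  # two-sided: doubled lower tail of U (matches 2*pwilcox convention)
  min(1, 2 * mean(Us <= U_min))
}

# Hertzian forward model, written directly from the force law.
oracle_hertz_force <- function(delta, E, nu = 0.5, theta_deg = 20.8) {
  tan(theta_deg * pi / 180) / sqrt(2) * E / (1 - nu^2) * delta^2
}

# Dominant period (nm) of a 1-D profile by FFT with parabolic
# interpolation around the spectral peak (excluding low frequencies).
oracle_profile_period <- function(profile, px_nm, min_period_nm = 20,
                                  max_period_nm = 200) {
  x <- profile - mean(profile)
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) / n                 # cycles per px
  keep <- f > 0 & f <= 0.5 &
    f >= px_nm / max_period_nm & f <= px_nm / min_period_nm
  idx <- which(keep)[which.max(P[keep])]
  # parabolic refinement in log power
  if (idx > 1 && idx < n) {
    lp <- log(pmax(P[(idx - 1):(idx + 1)], 1e-300))
    denom <- lp[1] - 2 * lp[2] + lp[3]
    shift <- if (abs(denom) > 0) 0.5 * (lp[1] - lp[3]) / denom else 0
    shift <- max(-0.5, min(0.5, shift))
  } else shift <- 0
  f_peak <- (idx - 1 + shift) / n
  px_nm / f_peak
}

# small helper: feature matrix for a list of ROIs
roi_features <- function(rois) {
  do.call(rbind, lapply(rois, extract_features))
}
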