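# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. All generator randomness flows through this, so no global state
# leaks between calls and reruns are bit-identical.
local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("`%s` must be > 0", name)
  if (nonneg && x < 0) stopf("`%s` must be >= 0", name)
  invisible(x)
}

# separable Gaussian blur with reflected edges; sigma in pixels
gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    idx <- seq_len(n)
    pad <- rbind(m[pmin(pmax(r:1, 1L), n), , drop = FALSE],
                 m,
                 m[pmin(pmax(n:(n - r + 1L), 1L), n), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[idx + (j - 1L), , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(mat))))
}

# radius-`r` box mean filter (used for local pooling), reflected edges
box_mean <- function(mat, r) {
  n <- 2L * r + 1L
  k <- rep(1 / n, n)
  sm1 <- function(m) {
    nr <- nrow(m)
    idx <- seq_len(nr)
    pad <- rbind(m[pmin(pmax(r:1, 1L), nr), , drop = FALSE],
                 m,
                 m[pmin(pmax(nr:(nr - r + 1L), 1L), nr), , drop = FALSE])
    out <- matrix(0, nr, ncol(m))
    for (j in seq_len(n)) out <- out + k[j] * pad[idx + (j - 1L), , drop = FALSE]
    out
  }
  t(sm1(t(sm1(mat))))
}
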