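# Independent brute-force oracles, coded scalar-by-scalar on purpose so they
# share nothing with the package's vectorized implementations.

# Scalar reflect padding lookup (mirror without repeating the edge pixel).
oracle_lookup <- function(m, i, j, padding) {
  h <- nrow(m); w <- ncol(m)
  fold <- function(k, n) {
    if (n == 1) return(1)
    while (k < 1 || k > n) {
      if (k < 1) k <- 2 - k
      if (k > n) k <- 2 * n - k
    }
    k
  }
  if (padding == "zero") {
    if (i < 1 || i > h || j < 1 || j > w) return(0)
    return(m[i, j])
  }
  if (padding == "edge") {
    return(m[min(max(i, 1), h), min(max(j, 1), w)])
  }
  m[fold(i, h), fold(j, w)]
}

# Quadruple-loop bilateral filter; set sigma_range = NULL for the pure
# Gaussian (spatial-only) filter.
oracle_neighborhood_filter <- function(m, sigma_spatial, sigma_range, radius,
                                       padding = "reflect") {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      num <- 0; den <- 0
      for (di in -radius:radius) {
        for (dj in -radius:radius) {
          fx <- oracle_lookup(m, i + di, j + dj, padding)
          wgt <- exp(-(di^2 + dj^2) / (2 * sigma_spatial^2))
          if (!is.null(sigma_range)) {
            wgt <- wgt * exp(-(fx - m[i, j])^2 / (2 * sigma_range^2))
          }
          num <- num + wgt * fx
          den <- den + wgt
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

random_test_image <- function(h, w, seed, range = c(0, 255)) {
  set.seed(seed)
  echo_image(matrix(runif(h * w, range[1], range[2]), h, w), range)
}

total_variation <- function(img) {
  m <- unclass(img)
  sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
}

step_image <- function(h = 8, w = 8, lo = 50, hi = 200) {
  m <- matrix(lo, h, w)
  m[, (floor(w / 2) + 1):w] <- hi
  echo_image(m)
}
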