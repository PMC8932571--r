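# Shared fixtures, all generated in code.

# A circular Gaussian RF centered in a size_px grid.
fixture_rf <- function(sigma_px = 8, size_px = 64, pixel_pitch = 7.5,
                       center = NULL) {
  center <- center %||% rep((size_px - 1) / 2, 2)
  gaussian_rf(center, diag(sigma_px^2, 2), pixel_pitch = pixel_pitch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# An RF so flat that G ~ 1 over the whole (small) grid: flat-weight limit.
fixture_flat_rf <- function(pixel_pitch = 7.5) {
  gaussian_rf(c(0, 0), diag(1e12, 2), pixel_pitch = pixel_pitch)
}

# Natural-like standardized images at the package's default study
# conditions.
fixture_images <- function(n = 300, size_px = 64, seed = 42) {
  generate_images(n, size_px = size_px, seed = seed)
}

# Naive double-loop oracles for the two image statistics (independent of
# the vectorized implementation path).
oracle_imean <- function(image, rf, n_sigma = 3) {
  si <- solve(rf$sigma)
  acc <- 0; N <- 0
  for (row in seq_len(nrow(image))) {
    for (col in seq_len(ncol(image))) {
      d <- c(col - 1, row - 1) - rf$mu
      q <- drop(t(d) %*% si %*% d)
      if (q <= n_sigma^2) {
        acc <- acc + exp(-q / 2) * image[row, col]
        N <- N + 1
      }
    }
  }
  acc / N
}

oracle_lsc <- function(image, rf, n_sigma = 3) {
  si <- solve(rf$sigma)
  vals <- c()
  for (row in seq_len(nrow(image))) {
    for (col in seq_len(ncol(image))) {
      d <- c(col - 1, row - 1) - rf$mu
      q <- drop(t(d) %*% si %*% d)
      if (q <= n_sigma^2) vals <- c(vals, exp(-q / 2) * image[row, col])
    }
  }
  sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1))
}

# Best rank-1 approximation by alternating power iteration (independent
# oracle for the SVD-based factorization).
oracle_rank1 <- function(M, iters = 500) {
  v <- rnorm(ncol(M)); v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    u <- M %*% v; u <- u / sqrt(sum(u^2))
    v <- t(M) %*% u; v <- v / sqrt(sum(v^2))
  }
  list(u = as.numeric(u), v = as.numeric(v),
       s = drop(t(u) %*% M %*% v))
}

# Numeric inverse of the softplus output stage.
softplus_inv <- function(r, a1, a2, a3) {
  log(expm1(pmax(r / a1, 1e-300))) / a2 - a3
}
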