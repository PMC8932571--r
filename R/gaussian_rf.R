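#' Two-dimensional Gaussian receptive field
#'
#' Parameterizes the spatial receptive field of a cell as a 2D Gaussian
#' with center `mu` (pixel coordinates, 0-based at pixel centers,
#' `x = column - 1`, `y = row - 1`), a 2x2 symmetric positive-definite
#' covariance `sigma` (pixel^2), and the physical pixel pitch. The kernel
#' is peak-normalized, `G(x) = exp(-1/2 (x - mu)' sigma^-1 (x - mu))`,
#' i.e. amplitude 1 and offset 0; only relative weights matter for the
#' image statistics built on it.
#'
#' @param mu numeric length-2, center `(x, y)` in pixels.
#' @param sigma 2x2 symmetric positive-definite covariance matrix, pixel^2.
#' @param pixel_pitch micrometers per pixel.
#' @return A `gaussian_rf` object.
#' @export
gaussian_rf <- function(mu, sigma, pixel_pitch = 7.5) {
  mu <- as.numeric(mu)
  if (length(mu) != 2 || any(!is.finite(mu)))
    stop("`mu` must be two finite numbers (x, y)", call. = FALSE)
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == c(2, 2)) || any(!is.finite(sigma)))
    stop("`sigma` must be a finite 2x2 matrix", call. = FALSE)
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(abs(sigma)))
    stop("`sigma` must be symmetric", call. = FALSE)
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("`sigma` must be positive definite", call. = FALSE)
  stop_if_not_scalar_number(pixel_pitch, "pixel_pitch")
  if (pixel_pitch <= 0) stop("`pixel_pitch` must be positive", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, pixel_pitch = pixel_pitch),
            class = "gaussian_rf")
}

#' @export
print.gaussian_rf <- function(x, ...) {
  cat(sprintf("<gaussian_rf> center (%.2f, %.2f) px, diameter %.1f um\n",
              x$mu[1], x$mu[2], effective_diameter(x)))
  invisible(x)
}

# Squared Mahalanobis distance of every pixel center of an ny x nx grid
# from the RF center; returned as an ny x nx matrix.
rf_mahalanobis_sq <- function(rf, dim) {
  ny <- dim[1]; nx <- dim[2]
  xs <- seq_len(nx) - 1
  ys <- seq_len(ny) - 1
  dx <- matrix(rep(xs, each = ny), ny, nx) - rf$mu[1]
  dy <- matrix(rep(ys, times = nx), ny, nx) - rf$mu[2]
  si <- solve(rf$sigma)
  si[1, 1] * dx^2 + 2 * si[1, 2] * dx * dy + si[2, 2] * dy^2
}

#' Evaluate the peak-normalized Gaussian kernel on a pixel grid
#'
#' @param rf a [gaussian_rf].
#' @param dim integer length-2, grid size `(ny, nx)` = `(rows, cols)`.
#' @return An `ny x nx` matrix of weights in (0, 1].
#' @export
rf_weights <- function(rf, dim) {
  exp(-0.5 * rf_mahalanobis_sq(rf, dim))
}

#' Elliptical contour mask of a Gaussian receptive field
#'
#' Marks pixels whose centers fall inside the `n_sigma` Mahalanobis
#' ellipse, `(x - mu)' sigma^-1 (x - mu) <= n_sigma^2`. The number of
#' selected pixels `N` (the normalizer of the I_mean/LSC statistics) is
#' attached as attribute `N`.
#'
#' @param rf a [gaussian_rf].
#' @param n_sigma contour level in units of sigma (default 3).
#' @param dim grid size `(ny, nx)`.
#' @return Logical `ny x nx` matrix with attribute `N` = number of `TRUE`
#'   pixels.
#' @export
contour_mask <- function(rf, n_sigma = 3, dim) {
  stop_if_not_scalar_number(n_sigma, "n_sigma")
  if (n_sigma <= 0) stop("`n_sigma` must be positive", call. = FALSE)
  m <- rf_mahalanobis_sq(rf, dim) <= n_sigma^2
  attr(m, "N") <- sum(m)
  m
}

#' Effective receptive-field diameter
#'
#' The diameter is `d = sqrt(a * b)`, where `a` and `b` are the major and
#' minor axis lengths (full axes, i.e. twice the semi-axes) of the
#' 1.5-sigma contour ellipse, converted to micrometers. For a circular
#' Gaussian with SD `s` pixels this gives `d = 3 * s * pixel_pitch`.
#'
#' @param rf a [gaussian_rf].
#' @param n_sigma contour level defining the ellipse (default 1.5).
#' @return Diameter in micrometers.
#' @export
effective_diameter <- function(rf, n_sigma = 1.5) {
  ev <- eigen(rf$sigma, symmetric = TRUE, only.values = TRUE)$values
  a <- 2 * n_sigma * sqrt(ev[1])
  b <- 2 * n_sigma * sqrt(ev[2])
  sqrt(a * b) * rf$pixel_pitch
}

#' Fit a 2D Gaussian to a spatial receptive-field map
#'
#' Least-squares fit of `A * exp(-1/2 (x-mu)' sigma^-1 (x-mu)) + B` to a
#' spatial map (e.g. the spatial factor of an STA). The covariance is
#' parameterized through its Cholesky factor so it stays positive
#' definite, and the amplitude `A` and offset `B` are profiled out by
#' linear least squares at every step. The returned object is normalized
#' to `A = 1`, `B = 0` (the peak-normalized kernel); the fitted amplitude,
#' offset, residual and convergence info are kept as attributes.
#'
#' @param spatial_rf numeric matrix (a `spatial_rf` from [separate_sta()]
#'   or any spatial map); by convention its peak-magnitude pixel is
#'   positive.
#' @param pixel_pitch micrometers per pixel (taken from the input
#'   attribute if present).
#' @param maxit maximum iterations for each optimizer pass.
#' @return A [gaussian_rf] with attributes `amplitude`, `offset`,
#'   `residual` (sum of squares), `converged`.
#' @export
fit_gaussian_rf <- function(spatial_rf, pixel_pitch = NULL, maxit = 2000) {
  pitch <- pixel_pitch %||% attr(spatial_rf, "pixel_pitch") %||% 7.5
  z <- unclass(as.matrix(spatial_rf))
  if (any(!is.finite(z))) stop("spatial map must be finite", call. = FALSE)
  if (sd(as.vector(z)) == 0)
    stop("cannot fit a Gaussian to a constant map", call. = FALSE)
  ny <- nrow(z); nx <- ncol(z)
  xs <- rep(seq_len(nx) - 1, each = ny)
  ys <- rep(seq_len(ny) - 1, times = nx)
  zv <- as.vector(z)

  # moment-based initialization from the positive part of the map
  # (sign convention puts the peak positive)
  w0 <- pmax(zv - quantile(zv, 0.5), 0)
  if (sum(w0) == 0) w0 <- abs(zv)
  w0 <- w0 / sum(w0)
  mx <- sum(w0 * xs); my <- sum(w0 * ys)
  vx <- max(sum(w0 * (xs - mx)^2), 0.25)
  vy <- max(sum(w0 * (ys - my)^2), 0.25)
  cxy <- sum(w0 * (xs - mx) * (ys - my))
  # clamp initial covariance to a valid Cholesky
  S0 <- matrix(c(vx, cxy, cxy, vy), 2, 2)
  ev <- eigen(S0, symmetric = TRUE)
  ev$values <- pmax(ev$values, 0.1)
  S0 <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
  L0 <- t(chol(S0))
  theta0 <- c(mx, my, log(L0[1, 1]), L0[2, 1], log(L0[2, 2]))

  # residual with A, B profiled out by linear LS
  obj <- function(theta) {
    dx <- xs - theta[1]; dy <- ys - theta[2]
    l11 <- exp(theta[3]); l21 <- theta[4]; l22 <- exp(theta[5])
    # sigma^-1 = L^-T L^-1 with L = [[l11,0],[l21,l22]]
    u <- dx / l11
    v <- (dy - l21 * u) / l22
    g <- exp(-0.5 * (u^2 + v^2))
    # LS for A, B
    gm <- mean(g); zm <- mean(zv)
    den <- sum((g - gm)^2)
    if (den < 1e-300) return(sum((zv - zm)^2))
    A <- sum((g - gm) * (zv - zm)) / den
    B <- zm - A * gm
    sum((A * g + B - zv)^2)
  }

  fit <- optim(theta0, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-12))
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-12))
  th <- fit$par
  l11 <- exp(th[3]); l21 <- th[4]; l22 <- exp(th[5])
  L <- matrix(c(l11, l21, 0, l22), 2, 2)
  sigma <- L %*% t(L)
  # recover profiled A, B for the metadata
  dx <- xs - th[1]; dy <- ys - th[2]
  u <- dx / l11; v <- (dy - l21 * u) / l22
  g <- exp(-0.5 * (u^2 + v^2))
  gm <- mean(g); zm <- mean(zv)
  A <- sum((g - gm) * (zv - zm)) / sum((g - gm)^2)
  B <- zm - A * gm

  out <- gaussian_rf(mu = th[1:2], sigma = sigma, pixel_pitch = pitch)
  attr(out, "amplitude") <- A
  attr(out, "offset") <- B
  attr(out, "residual") <- fit$value
  attr(out, "converged") <- fit$convergence == 0
  if (fit$convergence != 0)
    warning("Gaussian RF fit did not converge; result flagged", call. = FALSE)
  out
}
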