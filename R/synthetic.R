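#' Generate contrast-normalized natural-like images
#'
#' Images are Gaussian random fields with a power-law amplitude spectrum
#' `|A(f)| ~ f^-spectral_exponent` (0 = spatially white, 1 approximates
#' the 1/f statistics of natural scenes), multiplied by a slowly varying
#' log-normal contrast envelope, and standardized to zero-mean Weber
#' contrast with standard deviation `target_sd_fraction`, clipped to
#' \[-1, +1\] via [standardize_contrast()].
#'
#' The envelope reproduces a well-documented property of photographs
#' that a stationary Gaussian field lacks: local contrast fluctuates
#' strongly across a scene (textured foliage next to flat sky), so
#' different images place very different amounts of spatial structure
#' inside a receptive field even at equal mean intensity. Without it,
#' second-order statistics are nearly identical across images and
#' spatial-contrast effects are invisible by construction. Setting
#' `contrast_inhomogeneity = 0` recovers the plain stationary field.
#'
#' The generator is a pure function of its arguments and the seed.
#'
#' @param n_images number of images (>= 2).
#' @param size_px pixels per side (>= 8).
#' @param pixel_pitch micrometers per pixel.
#' @param spectral_exponent power-law exponent of the amplitude spectrum.
#' @param contrast_inhomogeneity SD of the log contrast envelope
#'   (default 0.8; 0 disables the envelope).
#' @param envelope_exponent spectral exponent of the envelope field
#'   (default 2.5, i.e. much smoother than the image itself).
#' @param target_sd_fraction contrast SD as a fraction of the mean light
#'   level, in (0, 1] (default 0.5).
#' @param seed integer seed.
#' @return A list of [contrast_image]s, each with a `clip_fraction`
#'   attribute.
#' @export
generate_images <- function(n_images, size_px = 64, pixel_pitch = 7.5,
                            spectral_exponent = 1,
                            contrast_inhomogeneity = 0.8,
                            envelope_exponent = 2.5,
                            target_sd_fraction = 0.5,
                            seed = NULL) {
  if (!is.numeric(n_images) || n_images < 2)
    stop("`n_images` must be at least 2", call. = FALSE)
  if (!is.numeric(size_px) || size_px < 8)
    stop("`size_px` must be at least 8", call. = FALSE)
  if (target_sd_fraction <= 0 || target_sd_fraction > 1)
    stop("`target_sd_fraction` must lie in (0, 1]", call. = FALSE)
  if (contrast_inhomogeneity < 0)
    stop("`contrast_inhomogeneity` must be >= 0", call. = FALSE)
  n <- as.integer(size_px)
  # radial spatial-frequency grid (cycles/pixel), FFT layout
  f1 <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  amp <- ifelse(fr == 0, 0, fr^(-spectral_exponent))
  amp_env <- ifelse(fr == 0, 0, fr^(-envelope_exponent))
  grf <- function(amplitude) {
    wn <- matrix(rnorm(n * n), n, n)
    x <- Re(fft(fft(wn) * amplitude, inverse = TRUE)) / (n * n)
    x / sd(as.vector(x))
  }
  with_seed(seed, {
    lapply(seq_len(n_images), function(i) {
      x <- grf(amp)
      if (contrast_inhomogeneity > 0)
        x <- x * exp(contrast_inhomogeneity * grf(amp_env))
      standardize_contrast(x, target_sd = target_sd_fraction,
                           pixel_pitch = pixel_pitch)
    })
  })
}

#' Binary checkerboard white-noise movie
#'
#' Spatiotemporal white noise on a checkerboard layout: each square is
#' independently +1 or -1 (100% Michelson contrast) with probability 1/2
#' on every frame.
#'
#' @param n_frames number of frames.
#' @param grid_px stimulus size in pixels per side; must be divisible by
#'   `square_px`.
#' @param square_px checker square size in pixels.
#' @param seed integer seed.
#' @param frame_rate frames per second (default 30).
#' @param pixel_pitch micrometers per pixel (default 30, i.e. one pixel
#'   per 30-um checker when `square_px = 1`).
#' @return A `stimulus_movie`: list with `frames` (array `ny x nx x
#'   n_frames` of -1/+1), `frame_rate`, `square_px`, `pixel_pitch`.
#' @export
generate_checkerboard_noise <- function(n_frames, grid_px, square_px = 1,
                                        seed = NULL, frame_rate = 30,
                                        pixel_pitch = 30) {
  if (n_frames < 1) stop("`n_frames` must be >= 1", call. = FALSE)
  if (grid_px %% square_px != 0)
    stop("`grid_px` must be divisible by `square_px`", call. = FALSE)
  ns <- as.integer(grid_px / square_px)
  frames <- with_seed(seed, {
    draws <- array(sample(c(-1, 1), ns * ns * n_frames, replace = TRUE),
                   dim = c(ns, ns, n_frames))
    if (square_px == 1) draws
    else {
      idx <- rep(seq_len(ns), each = square_px)
      draws[idx, idx, , drop = FALSE]
    }
  })
  structure(list(frames = frames, frame_rate = frame_rate,
                 square_px = as.integer(square_px),
                 pixel_pitch = pixel_pitch),
            class = "stimulus_movie")
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<stimulus_movie> %d x %d px, %d frames at %g Hz\n",
              d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}

#' Trial-to-trial noise specification for synthetic spike counts
#'
#' `"sub-poisson"` draws counts by binomial thinning: for an expected
#' count `lambda` the count is `Binomial(n, p)` with `n = round(lambda /
#' (1 - target_fano))` and `p = lambda / n`, giving integer counts with
#' mean `lambda` and Fano factor `1 - p` (approximately `target_fano`).
#' `"poisson"` gives Fano 1; `"deterministic"` returns `round(lambda)`.
#'
#' @param family one of `"sub-poisson"`, `"poisson"`, `"deterministic"`.
#' @param target_fano target Fano factor in (0, 1\] for the sub-Poisson
#'   family (default 0.3).
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(family = c("sub-poisson", "poisson", "deterministic"),
                       target_fano = 0.3) {
  family <- match.arg(family)
  if (family == "sub-poisson" &&
      (target_fano <= 0 || target_fano > 1))
    stop("`target_fano` must lie in (0, 1] for sub-Poisson noise",
         call. = FALSE)
  structure(list(family = family, target_fano = target_fano),
            class = "noise_spec")
}

# Draw integer counts for a vector of expected counts under a noise_spec.
draw_counts <- function(lambda, noise) {
  lambda <- pmax(lambda, 0)
  switch(noise$family,
    "deterministic" = round(lambda),
    "poisson" = rpois(length(lambda), lambda),
    "sub-poisson" = {
      p0 <- 1 - noise$target_fano
      n <- pmax(1L, as.integer(round(lambda / p0)))
      p <- pmin(1, lambda / n)
      rbinom(length(lambda), n, p)
    })
}

#' Ground-truth synthetic model cell
#'
#' Defines a generative retinal ganglion cell used to validate the
#' analysis pipeline. A `linear` cell drives its softplus output stage
#' with the signed receptive-field-weighted mean contrast; a `subunit`
#' cell pools rectified signals from a square grid of small Gaussian
#' subunits (a bipolar-cell-like tiling) inside the receptive field,
#' which makes it sensitive to local spatial contrast.
#'
#' Subunits are laid out on a square grid with spacing `subunit_spacing`,
#' keeping centers within the RF's 3-sigma contour; each subunit is a
#' circular Gaussian of SD `subunit_sigma` (normalized to unit sum, so a
#' subunit signal is a local weighted mean contrast), and its pooling
#' weight is the RF envelope at the subunit center.
#'
#' @param rf a [gaussian_rf] (ground truth).
#' @param polarity `"ON"` or `"OFF"`; the polarity sign multiplies the
#'   contrast so that e.g. dark stimuli drive OFF cells.
#' @param kind `"linear"` or `"subunit"`.
#' @param subunit_spacing subunit grid spacing, micrometers.
#' @param subunit_sigma subunit Gaussian SD, micrometers (> 0). On the
#'   receptive-field size convention (see [effective_diameter()]) a
#'   circular Gaussian of SD `s` has diameter `3 s`, so the subunit
#'   "size" is `3 * subunit_sigma`.
#' @param subunit_nonlinearity `"halfwave"` (default), `"softplus"`, or
#'   `"identity"` applied to the polarity-signed subunit drive.
#' @param output_params numeric `(a1, a2, a3)` of the softplus output
#'   stage `r = a1 * log(1 + exp(a2 * (d + a3)))`.
#' @param response_heterogeneity SD of a frozen per-image perturbation of
#'   the drive, as a fraction of the drive SD (default 0.4; 0 disables
#'   it). This reproducible, image-specific scatter stands for everything
#'   a Gaussian-receptive-field description misses in a real cell (fine
#'   receptive-field structure, surround effects); without it, synthetic
#'   responses are far more predictable than recorded ones.
#' @param noise a [noise_spec()].
#' @param temporal_filter optional unit-norm temporal kernel (most recent
#'   lag first) used for white-noise simulation; defaults to
#'   [biphasic_temporal_filter()].
#' @return A `synthetic_cell` object.
#' @export
synthetic_cell <- function(rf, polarity = c("OFF", "ON"),
                           kind = c("linear", "subunit"),
                           subunit_spacing = 30, subunit_sigma = 15,
                           subunit_nonlinearity = c("halfwave", "softplus",
                                                    "identity"),
                           output_params = c(a1 = 3, a2 = 25, a3 = 0),
                           response_heterogeneity = 0.4,
                           noise = noise_spec(),
                           temporal_filter = NULL) {
  stopifnot(inherits(rf, "gaussian_rf"), inherits(noise, "noise_spec"))
  polarity <- match.arg(polarity)
  kind <- match.arg(kind)
  subunit_nonlinearity <- match.arg(subunit_nonlinearity)
  if (kind == "subunit") {
    if (subunit_sigma <= 0) stop("`subunit_sigma` must be > 0", call. = FALSE)
    if (subunit_spacing <= 0) stop("`subunit_spacing` must be > 0", call. = FALSE)
  }
  output_params <- as.numeric(output_params)
  if (length(output_params) != 3 || output_params[1] < 0)
    stop("`output_params` must be (a1, a2, a3) with a1 >= 0", call. = FALSE)
  if (response_heterogeneity < 0)
    stop("`response_heterogeneity` must be >= 0", call. = FALSE)
  structure(list(rf = rf, polarity = polarity, kind = kind,
                 subunit_spacing = subunit_spacing,
                 subunit_sigma = subunit_sigma,
                 subunit_nonlinearity = subunit_nonlinearity,
                 output_params = output_params,
                 response_heterogeneity = response_heterogeneity,
                 noise = noise,
                 temporal_filter = temporal_filter),
            class = "synthetic_cell")
}

#' @export
print.synthetic_cell <- function(x, ...) {
  cat(sprintf("<synthetic_cell> %s %s cell, RF diameter %.0f um\n",
              x$polarity, x$kind, effective_diameter(x$rf)))
  invisible(x)
}

#' Biphasic temporal filter kernel
#'
#' A standard difference-of-alpha-functions kernel, unit Euclidean norm,
#' with a positive early peak and a later opposite-sign lobe. Lag 1 is
#' the most recent frame.
#'
#' @param n_lags number of time lags.
#' @param frame_rate frames per second.
#' @param peak_time latency of the main lobe, seconds.
#' @param trough_time latency of the opposite lobe, seconds.
#' @param biphasic_weight relative amplitude of the opposite lobe.
#' @return Unit-norm numeric vector of length `n_lags`.
#' @export
biphasic_temporal_filter <- function(n_lags = 20, frame_rate = 30,
                                     peak_time = 0.07, trough_time = 0.16,
                                     biphasic_weight = 0.6) {
  tt <- (seq_len(n_lags) - 0.5) / frame_rate
  alpha <- function(t, tau) (t / tau) * exp(1 - t / tau)
  k <- alpha(tt, peak_time) - biphasic_weight * alpha(tt, trough_time)
  k / sqrt(sum(k^2))
}

# Precompute the subunit pooling structure of a cell on a pixel grid:
# a (n_subunits x n_pixels) matrix of unit-sum subunit kernels and the
# RF-envelope pooling weights.
build_subunits <- function(cell, dim) {
  rf <- cell$rf
  pitch <- rf$pixel_pitch
  sp <- cell$subunit_spacing / pitch     # spacing, px
  ss <- cell$subunit_sigma / pitch       # SD, px
  ny <- dim[1]; nx <- dim[2]
  ev <- eigen(rf$sigma, symmetric = TRUE, only.values = TRUE)$values
  r3 <- 3 * sqrt(ev[1])                  # 3-sigma along the major axis
  gx <- rf$mu[1] + seq(-r3, r3, by = sp)
  gy <- rf$mu[2] + seq(-r3, r3, by = sp)
  centers <- expand.grid(x = gx, y = gy)
  si <- solve(rf$sigma)
  dxc <- centers$x - rf$mu[1]; dyc <- centers$y - rf$mu[2]
  q <- si[1, 1] * dxc^2 + 2 * si[1, 2] * dxc * dyc + si[2, 2] * dyc^2
  keep <- q <= 9 &
    centers$x >= 0 & centers$x <= nx - 1 &
    centers$y >= 0 & centers$y <= ny - 1
  centers <- centers[keep, , drop = FALSE]
  if (nrow(centers) == 0)
    stop("no subunit centers inside the receptive field on this grid",
         call. = FALSE)
  pool_w <- exp(-0.5 * q[keep])
  xs <- rep(seq_len(nx) - 1, each = ny)
  ys <- rep(seq_len(ny) - 1, times = nx)
  K <- matrix(0, nrow(centers), ny * nx)
  for (k in seq_len(nrow(centers))) {
    w <- exp(-((xs - centers$x[k])^2 + (ys - centers$y[k])^2) / (2 * ss^2))
    K[k, ] <- w / sum(w)
  }
  list(kernels = K, pool_w = pool_w, centers = centers)
}

# Generative drive of a cell for each image (before heterogeneity and
# the output nonlinearity).
cell_drives <- function(cell, images, subunits = NULL) {
  sgn <- if (cell$polarity == "OFF") -1 else 1
  if (cell$kind == "linear") {
    vapply(images, function(img) sgn * compute_imean(img, cell$rf),
           numeric(1))
  } else {
    su <- subunits %||% build_subunits(cell, dim(images[[1]]))
    nl <- switch(cell$subunit_nonlinearity,
                 halfwave = function(u) pmax(u, 0),
                 softplus = function(u) log1p(exp(pmin(u * 8, 50))) / 8,
                 identity = identity)
    vapply(images, function(img) {
      u <- sgn * as.numeric(su$kernels %*% as.vector(unclass(img)))
      sum(su$pool_w * nl(u)) / sum(su$pool_w)
    }, numeric(1))
  }
}

#' Simulate spike-count responses to flashed images
#'
#' Evaluates the cell's generative drive for each image (signed I_mean
#' for linear cells; pooled rectified subunit signals for subunit cells),
#' adds the frozen per-image heterogeneity, passes the result through the
#' softplus output stage, and draws per-trial integer counts under the
#' cell's noise model. The heterogeneity realization and the trial noise
#' are both functions of `seed`, so the same seed reproduces the table
#' bit for bit.
#'
#' @param cell a [synthetic_cell].
#' @param images list of [contrast_image]s.
#' @param n_trials trials per image (>= 1).
#' @param seed integer seed.
#' @return A [response_table] (`n_images x n_trials` integer matrix) with
#'   attribute `expected` holding the expected counts per image.
#' @export
simulate_flash_responses <- function(cell, images, n_trials, seed = NULL) {
  stopifnot(inherits(cell, "synthetic_cell"))
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  drives <- cell_drives(cell, images)
  a <- cell$output_params
  out <- with_seed(seed, {
    if (cell$response_heterogeneity > 0 && sd(drives) > 0)
      drives <- drives + rnorm(length(drives),
                               0, cell$response_heterogeneity * sd(drives))
    lambda <- softplus(drives, a[1], a[2], a[3])
    counts <- vapply(seq_len(n_trials),
                     function(t) draw_counts(lambda, cell$noise),
                     numeric(length(lambda)))
    tab <- response_table(matrix(as.integer(counts),
                                 length(images), n_trials))
    attr(tab, "expected") <- lambda
    tab
  })
  out
}

#' Simulate a spike train under white-noise stimulation
#'
#' The movie is filtered by the cell's ground-truth spatial receptive
#' field (peak-normalized Gaussian weights averaged over the 3-sigma
#' contour, as in I_mean) and by its temporal kernel; the polarity sign
#' is carried by the temporal filter, as in the STA convention. The
#' resulting drive passes through the softplus output stage to give a
#' spike rate per frame, and spike counts per frame are Poisson, with
#' spike times placed uniformly within each frame.
#'
#' Because the receptive-field-averaged signal of a fine checkerboard is
#' much smaller than the drive produced by a flashed image, the drive is
#' rescaled to `drive_sd` standard deviations before the output stage
#' (the counterpart of contrast adaptation setting the operating point);
#' this keeps the rate modulation depth, and hence the STA
#' signal-to-noise ratio per spike, at a realistic level.
#'
#' @param cell a [synthetic_cell].
#' @param movie a [stimulus_movie] longer than the temporal kernel.
#' @param drive_sd operating-point SD of the filtered drive (default
#'   0.15, comparable to the spread of flash drives).
#' @param seed integer seed.
#' @return Sorted numeric vector of spike times in seconds.
#' @export
simulate_white_noise_spikes <- function(cell, movie, drive_sd = 0.15,
                                        seed = NULL) {
  stopifnot(inherits(cell, "synthetic_cell"),
            inherits(movie, "stimulus_movie"))
  d <- dim(movie$frames)
  tf <- cell$temporal_filter %||% biphasic_temporal_filter(
    n_lags = 20, frame_rate = movie$frame_rate)
  n_lags <- length(tf)
  if (d[3] <= n_lags)
    stop("movie shorter than the cell's temporal filter support",
         call. = FALSE)
  sgn <- if (cell$polarity == "OFF") -1 else 1
  k <- rf_window(cell$rf, d[1:2], 3)
  w <- numeric(d[1] * d[2])
  w[as.vector(k$mask)] <- k$G / k$N
  M <- matrix(movie$frames, d[1] * d[2], d[3])
  s <- as.numeric(crossprod(M, w))          # spatial signal per frame
  h <- sgn * tf
  drive <- numeric(d[3])
  for (l in seq_len(n_lags)) {
    drive[l:d[3]] <- drive[l:d[3]] + h[l] * s[seq_len(d[3] - l + 1L)]
  }
  drive[seq_len(n_lags - 1L)] <- 0          # incomplete history: silent
  s_dr <- sd(drive[n_lags:d[3]])
  if (s_dr > 0) drive <- drive * (drive_sd / s_dr)
  a <- cell$output_params
  rate <- softplus(drive, a[1], a[2], a[3]) # spikes per frame
  with_seed(seed, {
    n_per_frame <- rpois(d[3], rate)
    onsets <- (which(n_per_frame > 0) - 1) / movie$frame_rate
    counts <- n_per_frame[n_per_frame > 0]
    times <- rep(onsets, counts) + runif(sum(counts)) / movie$frame_rate
    sort(times)
  })
}
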