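#' Weber-contrast images
#'
#' A `contrast_image` is a numeric matrix of Weber contrast values
#' \eqn{C(x) = (L - L_{mean})/L_{mean}} (dimensionless, nominally in
#' \[-1, +1\]) together with the physical pixel pitch in micrometers per
#' pixel. Rows index the vertical (y) direction, columns the horizontal (x)
#' direction; pixel coordinates are 0-based at pixel centers, with
#' `x = column - 1` and `y = row - 1`.
#'
#' @param values numeric matrix of contrast values.
#' @param pixel_pitch physical size of one pixel, micrometers.
#' @return A `contrast_image` object (a matrix with attributes).
#' @export
contrast_image <- function(values, pixel_pitch = 7.5) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(values)))
    stop("contrast values must be finite", call. = FALSE)
  stop_if_not_scalar_number(pixel_pitch, "pixel_pitch")
  if (pixel_pitch <= 0)
    stop("`pixel_pitch` must be positive", call. = FALSE)
  structure(values,
            pixel_pitch = pixel_pitch,
            class = c("contrast_image", "matrix", "array"))
}

#' @export
print.contrast_image <- function(x, ...) {
  cat(sprintf("<contrast_image> %d x %d px, pitch %.3g um/px, range [%.3g, %.3g]\n",
              nrow(x), ncol(x), attr(x, "pixel_pitch"), min(x), max(x)))
  invisible(x)
}

pixel_pitch <- function(image) {
  p <- attr(image, "pixel_pitch")
  if (is.null(p)) stop("image has no pixel_pitch attribute", call. = FALSE)
  p
}

#' Convert a luminance image to Weber contrast
#'
#' Pixel-wise Weber contrast relative to a reference (typically the mean)
#' luminance: `C = (L - L_mean) / L_mean`.
#'
#' @param luminance numeric matrix of light levels (arbitrary units, >= 0).
#' @param L_mean reference luminance, must be positive. Defaults to the
#'   mean of `luminance`.
#' @param pixel_pitch micrometers per pixel of the resulting image.
#' @return A [contrast_image].
#' @export
to_weber_contrast <- function(luminance, L_mean = mean(luminance),
                              pixel_pitch = 7.5) {
  stop_if_not_scalar_number(L_mean, "L_mean")
  if (L_mean <= 0) stop("`L_mean` must be positive", call. = FALSE)
  contrast_image((luminance - L_mean) / L_mean, pixel_pitch = pixel_pitch)
}

#' Standardize an image to zero-mean contrast with a target SD
#'
#' Reproduces the display-preparation pipeline for flashed images: color
#' images are converted to grayscale with channel weights R:G:B = 30:59:11,
#' pixel values are shifted to zero mean and scaled so that the standard
#' deviation equals `target_sd` (in Weber-contrast units, i.e. as a fraction
#' of the mean light level), and finally the contrast is clipped to
#' `clip` (default \[-1, +1\], corresponding to 0% and 200% of the mean
#' light level on a display). The fraction of clipped pixels is reported in
#' the `clip_fraction` attribute of the result.
#'
#' @param image numeric matrix (grayscale) or 3-d array with the third
#'   dimension of length 3 (RGB), in arbitrary intensity units, or a
#'   [contrast_image].
#' @param target_sd standard deviation of the standardized contrast before
#'   clipping (default 0.5, i.e. 50% of the mean intensity).
#' @param clip length-2 numeric, lower and upper clip bounds in contrast
#'   units.
#' @param pixel_pitch micrometers per pixel of the result (taken from the
#'   input when it is a `contrast_image`).
#' @return A [contrast_image] with attribute `clip_fraction`.
#' @export
standardize_contrast <- function(image, target_sd = 0.5, clip = c(-1, 1),
                                 pixel_pitch = 7.5) {
  stop_if_not_scalar_number(target_sd, "target_sd")
  if (target_sd <= 0 || target_sd > 1)
    stop("`target_sd` must lie in (0, 1]", call. = FALSE)
  if (inherits(image, "contrast_image")) pixel_pitch <- pixel_pitch(image)
  if (is.array(image) && length(dim(image)) == 3) {
    if (dim(image)[3] != 3)
      stop("color images must have 3 channels", call. = FALSE)
    w <- c(30, 59, 11) / 100
    image <- image[, , 1] * w[1] + image[, , 2] * w[2] + image[, , 3] * w[3]
  }
  x <- unclass(as.matrix(image))
  s <- sd(as.vector(x))
  if (s == 0) stop("cannot standardize a constant image", call. = FALSE)
  x <- (x - mean(x)) * (target_sd / s)
  clipped <- x < clip[1] | x > clip[2]
  x <- pmin(pmax(x, clip[1]), clip[2])
  out <- contrast_image(x, pixel_pitch = pixel_pitch)
  attr(out, "clip_fraction") <- mean(clipped)
  out
}

#' Blur an image with a circular Gaussian filter
#'
#' The spatial scale follows the receptive-field size convention: it is
#' three times the standard deviation of the Gaussian kernel, in
#' micrometers. A scale of 0 returns the image unchanged. Convolution is
#' separable with reflective (mirror) boundary padding, so a constant
#' image is exactly invariant under smoothing.
#'
#' @param image a [contrast_image].
#' @param spatial_scale smoothing scale in micrometers (3 x kernel SD).
#' @return The smoothed [contrast_image].
#' @export
smooth_image <- function(image, spatial_scale) {
  stop_if_not_scalar_number(spatial_scale, "spatial_scale")
  if (spatial_scale < 0) stop("`spatial_scale` must be >= 0", call. = FALSE)
  if (spatial_scale == 0) return(image)
  pitch <- pixel_pitch(image)
  sigma_px <- (spatial_scale / 3) / pitch
  k <- gaussian_kernel_1d(sigma_px)
  x <- unclass(as.matrix(image))
  x <- convolve_sep(x, k)
  out <- contrast_image(x, pixel_pitch = pitch)
  out
}

# Normalized 1-d Gaussian kernel, truncated at ~3.5 sigma.
gaussian_kernel_1d <- function(sigma_px) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma_px)))
  k <- dnorm(seq(-r, r), sd = sigma_px)
  k / sum(k)
}

# Separable convolution with mirror padding (edge pixel not repeated:
# ... 3 2 | 1 2 3 ... n | n-1 n-2 ...).
convolve_sep <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  x <- conv_1d_cols(x, k, r)          # along rows (y)
  x <- t(conv_1d_cols(t(x), k, r))    # along columns (x)
  x
}

conv_1d_cols <- function(x, k, r) {
  n <- nrow(x)
  mirror <- function(i, n) {
    # reflect i (can be <1 or >n) into 1..n without repeating the edge
    i <- abs(i - 1L) %% (2L * (n - 1L))
    pmin(i, 2L * (n - 1L) - i) + 1L
  }
  if (n == 1L) {
    pad <- x[rep(1L, n + 2L * r), , drop = FALSE]
  } else {
    pad <- x[mirror(seq(1L - r, n + r), n), , drop = FALSE]
  }
  out <- matrix(0, n, ncol(x))
  for (j in seq_along(k)) {
    out <- out + k[j] * pad[seq(j, length.out = n), , drop = FALSE]
  }
  out
}
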