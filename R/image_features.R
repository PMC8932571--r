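#' Receptive-field-weighted mean intensity (I_mean)
#'
#' The linear drive of the LN model: the image is weighted by the
#' peak-normalized Gaussian receptive field and averaged over the `N`
#' pixels inside the 3-sigma contour,
#' `I_mean = (1/N) * sum_i G(x_i) * C(x_i)`.
#'
#' @param image a [contrast_image].
#' @param rf a [gaussian_rf].
#' @param n_sigma contour defining the pixel set (default 3).
#' @return The scalar I_mean.
#' @export
compute_imean <- function(image, rf, n_sigma = 3) {
  k <- rf_window(rf, dim(image), n_sigma)
  sum(k$G * image[k$mask]) / k$N
}

#' Local spatial contrast (LSC)
#'
#' The sample standard deviation (denominator `N - 1`) of the
#' receptive-field-weighted pixel contrasts inside the 3-sigma contour:
#' `LSC = sqrt( (1/(N-1)) * sum_i (G(x_i) C(x_i) - I_mean)^2 )`.
#' With `weighted_original = TRUE` the alternative measure is returned
#' instead: the G-weighted standard deviation of the unweighted image
#' (the difference between the two measures is small in practice).
#'
#' @param image a [contrast_image].
#' @param rf a [gaussian_rf].
#' @param n_sigma contour defining the pixel set (default 3).
#' @param weighted_original use the weighted-SD-of-original-image variant.
#' @return The scalar LSC (>= 0).
#' @export
compute_lsc <- function(image, rf, n_sigma = 3, weighted_original = FALSE) {
  k <- rf_window(rf, dim(image), n_sigma)
  if (k$N < 2)
    stop("LSC needs at least 2 pixels inside the contour", call. = FALSE)
  cvals <- image[k$mask]
  if (weighted_original) {
    m <- sum(k$G * cvals) / sum(k$G)
    return(sqrt(sum(k$G * (cvals - m)^2) / sum(k$G)))
  }
  wv <- k$G * cvals
  sqrt(sum((wv - mean(wv))^2) / (k$N - 1))
}

# Mask + kernel weights of an RF on a grid, restricted to the mask.
rf_window <- function(rf, dim, n_sigma = 3) {
  q <- rf_mahalanobis_sq(rf, dim)
  mask <- q <= n_sigma^2
  N <- sum(mask)
  if (N < 1)
    stop("receptive-field contour does not overlap the image", call. = FALSE)
  list(mask = mask, G = exp(-0.5 * q[mask]), N = N)
}

#' Feature table of I_mean and LSC for a set of images
#'
#' Computes, for each image, the mean intensity from the *original*
#' (unsmoothed) image and the local spatial contrast from the image
#' smoothed at `smoothing_scale` (0 = no smoothing, so both statistics
#' come from the same image).
#'
#' The `i_mean` column is the model drive `F_LN`: for OFF cells it is the
#' sign-flipped I_mean, so that dark stimuli produce a positive drive and
#' the monotone-increasing softplus nonlinearity applies to both
#' polarities. (This is equivalent to letting the unit-norm spatial
#' filter of an OFF cell keep its negative sign instead of the
#' positive-peak normalization used here.) The LSC is a magnitude and is
#' unaffected by polarity.
#'
#' @param images list of [contrast_image]s.
#' @param rf a [gaussian_rf].
#' @param smoothing_scale smoothing scale in micrometers passed to
#'   [smooth_image()] before the LSC computation.
#' @param n_sigma contour defining the pixel set (default 3).
#' @param polarity `"ON"` (drive = I_mean) or `"OFF"` (drive = -I_mean).
#' @return A data.frame with columns `image_id`, `i_mean`, `lsc`,
#'   `smoothing_scale`.
#' @export
feature_table <- function(images, rf, smoothing_scale = 0, n_sigma = 3,
                          polarity = c("ON", "OFF")) {
  polarity <- match.arg(polarity)
  stopifnot(is.list(images), length(images) >= 1)
  dim1 <- dim(images[[1]])
  k <- rf_window(rf, dim1, n_sigma)
  if (k$N < 2)
    stop("LSC needs at least 2 pixels inside the contour", call. = FALSE)
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    if (!all(dim(img) == dim1))
      stop("all images must share the same dimensions", call. = FALSE)
    wv <- k$G * img[k$mask]
    i_mean <- sum(wv) / k$N
    simg <- if (smoothing_scale > 0) smooth_image(img, smoothing_scale) else img
    wvs <- k$G * simg[k$mask]
    lsc <- sqrt(sum((wvs - mean(wvs))^2) / (k$N - 1))
    data.frame(image_id = i, i_mean = i_mean, lsc = lsc,
               smoothing_scale = smoothing_scale)
  })
  out <- do.call(rbind, rows)
  if (polarity == "OFF") out$i_mean <- -out$i_mean
  out
}
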