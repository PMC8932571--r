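#' Neighbor pairs in the I_mean ordering
#'
#' Orders images by their I_mean value (stable sort; ties keep image-id
#' order) and forms all adjacent pairs, computing the differences
#' (next - current, i.e. hi - lo) in I_mean, LSC and trial-averaged spike
#' count. Because neighboring images have nearly equal I_mean, the
#' differences isolate spatial-contrast effects on the response from
#' mean-intensity effects.
#'
#' @param features data.frame with columns `image_id`, `i_mean`, `lsc`
#'   (e.g. from [feature_table()]).
#' @param mean_counts numeric vector of trial-averaged spike counts, one
#'   per row of `features`.
#' @return A `pair_table` data.frame with columns `image_lo`, `image_hi`,
#'   `d_imean`, `d_lsc`, `d_spikes`; `nrow = n_images - 1`.
#' @export
make_pairs <- function(features, mean_counts) {
  stopifnot(is.data.frame(features),
            all(c("image_id", "i_mean", "lsc") %in% names(features)),
            length(mean_counts) == nrow(features))
  n <- nrow(features)
  if (n < 2) stop("need at least 2 images to form pairs", call. = FALSE)
  o <- order(features$i_mean, features$image_id)
  im <- features$i_mean[o]
  ls <- features$lsc[o]
  sp <- mean_counts[o]
  id <- features$image_id[o]
  out <- data.frame(
    image_lo = id[-n], image_hi = id[-1],
    d_imean = diff(im), d_lsc = diff(ls), d_spikes = diff(sp))
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Correlations among paired differences
#'
#' Pearson correlations between the neighbor-pair difference vectors, and
#' the least-squares slope of `d_spikes` on `d_lsc`. A sizeable
#' `r_dlsc_dspikes` with negligible `r_dimean_dspikes` indicates that
#' local spatial contrast drives the response beyond mean intensity.
#' Entries whose inputs are constant are returned as `NA` with a warning.
#'
#' @param pairs a `pair_table` from [make_pairs()].
#' @return List with `r_dimean_dspikes`, `r_dlsc_dspikes`,
#'   `r_dimean_dlsc`, `slope_dlsc_dspikes`, `n_pairs`.
#' @export
pair_correlations <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("d_imean", "d_lsc", "d_spikes") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 pairs", call. = FALSE)
  slope <- if (sd(pairs$d_lsc) == 0) NA_real_ else
    sum((pairs$d_lsc - mean(pairs$d_lsc)) *
          (pairs$d_spikes - mean(pairs$d_spikes))) /
    sum((pairs$d_lsc - mean(pairs$d_lsc))^2)
  list(
    r_dimean_dspikes = safe_cor(pairs$d_imean, pairs$d_spikes,
                                "corr(d_imean, d_spikes)"),
    r_dlsc_dspikes = safe_cor(pairs$d_lsc, pairs$d_spikes,
                              "corr(d_lsc, d_spikes)"),
    r_dimean_dlsc = safe_cor(pairs$d_imean, pairs$d_lsc,
                             "corr(d_imean, d_lsc)"),
    slope_dlsc_dspikes = slope,
    n_pairs = nrow(pairs))
}
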