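#' Per-image, per-trial spike-count table
#'
#' @param counts nonnegative integer matrix, images in rows, trials in
#'   columns.
#' @param count_window length-2 numeric, counting window (start, end) in
#'   milliseconds relative to image onset (metadata only).
#' @return A `response_table` object.
#' @export
response_table <- function(counts, count_window = c(0, 300)) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (count_window[1] >= count_window[2])
    stop("count window start must precede its end", call. = FALSE)
  structure(counts, count_window = count_window,
            class = c("response_table", "matrix", "array"))
}

#' @export
print.response_table <- function(x, ...) {
  w <- attr(x, "count_window")
  cat(sprintf("<response_table> %d images x %d trials, window [%g, %g) ms\n",
              nrow(x), ncol(x), w[1], w[2]))
  invisible(x)
}

#' Count spikes in an onset-aligned window
#'
#' Counts spikes with onset-relative times in the half-open window
#' `[start, end)` milliseconds: a spike exactly at the window end is
#' excluded. The species presets follow the two counting conventions in
#' use: salamander `[0, 300)` ms (image onset to 100 ms past the 200-ms
#' offset), mouse `[0, 250)` ms (onset to 50 ms past offset).
#'
#' @param spike_times list (one element per image) of lists (one element
#'   per trial) of numeric spike times in milliseconds relative to image
#'   onset; or, for a single trial, a numeric vector.
#' @param window length-2 numeric `(start, end)` ms, or a species preset
#'   via `species`.
#' @param species optional `"salamander"` or `"mouse"`; sets `window` to
#'   the preset when `window` is missing.
#' @return A [response_table] (or a single count for a numeric-vector
#'   input).
#' @export
count_spikes <- function(spike_times, window = NULL, species = NULL) {
  if (is.null(window)) {
    window <- switch(species %||% "salamander",
                     salamander = c(0, 300), mouse = c(0, 250),
                     stop("unknown species preset", call. = FALSE))
  }
  count1 <- function(t) sum(t >= window[1] & t < window[2])
  if (is.numeric(spike_times)) return(count1(spike_times))
  counts <- t(vapply(spike_times,
                     function(trials) vapply(trials, count1, integer(1)),
                     integer(length(spike_times[[1]]))))
  response_table(counts, count_window = window)
}

#' Fano factors of trial spike counts
#'
#' Per-image Fano factor = sample variance / mean of the trial counts.
#' Images with zero total spikes are excluded from the Fano statistics
#' (their ratio is undefined); the cell-level Fano factor is the mean of
#' the per-image factors over the included images.
#'
#' @param table a [response_table] with at least 2 trials.
#' @return List with `per_image` (NA for excluded images), `cell`
#'   (mean over included images), `n_included`.
#' @export
fano_factors <- function(table) {
  if (ncol(table) < 2)
    stop("Fano factors need at least 2 trials", call. = FALSE)
  m <- rowMeans(table)
  v <- apply(table, 1, var)
  ff <- ifelse(m > 0, v / m, NA_real_)
  list(per_image = ff, cell = mean(ff, na.rm = TRUE),
       n_included = sum(!is.na(ff)))
}

#' Polarity from full-field black/white responses (salamander)
#'
#' OFF if `n_black / n_white > 3`, ON if `n_white / n_black > 3`, else
#' ON-OFF. A zero denominator counts as an infinite ratio (the cell is
#' classified by the nonzero side); two zero counts give ON-OFF.
#'
#' @param n_black,n_white spike counts to full-field black and white
#'   steps (+/-100% contrast).
#' @return `"OFF"`, `"ON"`, or `"ON-OFF"`.
#' @export
classify_polarity_salamander <- function(n_black, n_white) {
  if (n_black < 0 || n_white < 0) stop("counts must be >= 0", call. = FALSE)
  ratio_bw <- if (n_white == 0) Inf else n_black / n_white
  ratio_wb <- if (n_black == 0) Inf else n_white / n_black
  if (n_black == 0 && n_white == 0) return("ON-OFF")
  if (ratio_bw > 3) "OFF" else if (ratio_wb > 3) "ON" else "ON-OFF"
}

#' Polarity from responses to bright vs dark images (mouse)
#'
#' `R_on` is the mean count over images with positive I_mean, `R_off`
#' over images with negative I_mean (zero-I_mean images are excluded).
#' ON if `R_on > 2 R_off`, OFF if `R_off > 2 R_on`, else ON-OFF.
#'
#' @param table a [response_table].
#' @param i_mean numeric vector of per-image I_mean values.
#' @return `"ON"`, `"OFF"`, or `"ON-OFF"`.
#' @export
classify_polarity_mouse <- function(table, i_mean) {
  stopifnot(length(i_mean) == nrow(table))
  m <- rowMeans(table)
  r_on <- mean(m[i_mean > 0])
  r_off <- mean(m[i_mean < 0])
  if (!is.finite(r_on) || !is.finite(r_off))
    stop("need images with both positive and negative I_mean", call. = FALSE)
  if (r_on > 2 * r_off) "ON" else if (r_off > 2 * r_on) "OFF" else "ON-OFF"
}

#' Symmetrized odd/even trial reliability
#'
#' Splits trials by parity and compares the two per-image mean-count
#' vectors with a symmetrized coefficient of determination,
#' `R2_sym = 1 - sum (o_i - e_i)^2 / sum ((o_i - m)^2 + (e_i - m)^2)`,
#' where `m` is the grand mean of both halves. Identical halves give 1;
#' independent noise gives approximately 0.
#'
#' @param table a [response_table] with at least 2 trials.
#' @return The symmetrized R-squared.
#' @export
odd_even_reliability <- function(table) {
  if (ncol(table) < 2)
    stop("reliability needs at least 2 trials", call. = FALSE)
  odd <- seq(1, ncol(table), by = 2)
  even <- seq(2, ncol(table), by = 2)
  o <- rowMeans(table[, odd, drop = FALSE])
  e <- rowMeans(table[, even, drop = FALSE])
  m <- mean(c(o, e))
  den <- sum((o - m)^2 + (e - m)^2)
  if (den == 0) return(1)
  1 - sum((o - e)^2) / den
}

#' Response-strength inclusion filter
#'
#' A cell is included when its best image drives it strongly enough:
#' maximum per-image trial-averaged count >= 5 spikes (salamander) or
#' >= 6 spikes (mouse); mouse cells additionally require odd/even
#' reliability >= 0.5.
#'
#' @param table a [response_table].
#' @param species `"salamander"` or `"mouse"`.
#' @return List with `include` (logical) and `reasons` (character vector
#'   of failed checks, empty when included).
#' @export
inclusion_filter <- function(table, species = c("salamander", "mouse")) {
  species <- match.arg(species)
  reasons <- character()
  max_mean <- max(rowMeans(table))
  if (species == "salamander") {
    if (max_mean < 5) reasons <- c(reasons, "max mean count < 5")
  } else {
    if (max_mean < 6) reasons <- c(reasons, "max mean count < 6")
    rel <- odd_even_reliability(table)
    if (rel < 0.5) reasons <- c(reasons, "reliability < 0.5")
  }
  list(include = length(reasons) == 0, reasons = reasons)
}

#' Functional clustering of cells by RF size and temporal kinetics
#'
#' Projects each cell's temporal filter onto the first principal
#' component of all filters, z-scores the (diameter, PC1-projection)
#' pair, and clusters with seeded k-means (multiple initializations, best
#' inertia kept). With k = 4 this separates small/large x slow/fast OFF
#' cells.
#'
#' @param diameters numeric vector of effective RF diameters, micrometers.
#' @param temporal_filters matrix of temporal filters, one row per cell.
#' @param k number of clusters (default 4).
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return List with `labels`, `pc1` (projections), `centers` (on the
#'   z-scored feature space).
#' @export
cluster_cells <- function(diameters, temporal_filters, k = 4, seed = NULL,
                          nstart = 20) {
  temporal_filters <- as.matrix(temporal_filters)
  stopifnot(length(diameters) == nrow(temporal_filters))
  if (length(diameters) < k)
    stop("need at least k cells", call. = FALSE)
  pc <- prcomp(temporal_filters, center = TRUE, scale. = FALSE)
  pc1 <- pc$x[, 1]
  feats <- scale(cbind(diameter = diameters, pc1 = pc1))
  km <- with_seed(seed, kmeans(feats, centers = k, nstart = nstart))
  list(labels = km$cluster, pc1 = pc1, centers = km$centers)
}
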