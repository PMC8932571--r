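#' Spike-triggered average from a white-noise run
#'
#' Averages the stimulus segments preceding each spike. A spike is
#' assigned to the last frame whose onset precedes (or coincides with) it;
#' only spikes with at least `lag_window` of stimulus history qualify.
#' The number of time lags is `ceiling(lag_window * frame_rate / 1000)`
#' (20 frames for the default 660 ms at 30 Hz).
#'
#' @param movie a [stimulus_movie].
#' @param spikes numeric vector of spike times in seconds from movie onset.
#' @param lag_window history window in milliseconds (default 660).
#' @return An `sta` object: 3-d array `lags x ny x nx` (lag 1 = the frame
#'   containing the spike, increasing lags reach further into the past)
#'   with attributes `n_spikes`, `frame_rate`, `lag_window`, `pixel_pitch`.
#' @export
compute_sta <- function(movie, spikes, lag_window = 660) {
  stopifnot(inherits(movie, "stimulus_movie"))
  fr <- movie$frame_rate
  nf <- dim(movie$frames)[3]
  n_lags <- as.integer(ceiling(lag_window * fr / 1000))
  if (nf < n_lags)
    stop("movie shorter than the requested lag window", call. = FALSE)
  spikes <- as.numeric(spikes)
  frame_of <- pmin(floor(spikes * fr) + 1L, nf)
  keep <- spikes >= 0 & spikes <= nf / fr & frame_of >= n_lags
  n_spk <- sum(keep)
  if (n_spk < 1)
    stop(sprintf("no qualifying spikes (%d supplied, 0 with %g ms of history)",
                 length(spikes), lag_window), call. = FALSE)
  cnt <- tabulate(frame_of[keep], nbins = nf)
  ny <- dim(movie$frames)[1]; nx <- dim(movie$frames)[2]
  M <- matrix(movie$frames, ny * nx, nf)
  sta <- array(0, dim = c(n_lags, ny, nx))
  for (l in seq_len(n_lags)) {
    # lag l uses frame (spike frame) - (l - 1)
    v <- M[, seq_len(nf - l + 1L), drop = FALSE] %*% cnt[l:nf]
    sta[l, , ] <- matrix(v / n_spk, ny, nx)
  }
  structure(sta,
            n_spikes = n_spk, frame_rate = fr, lag_window = lag_window,
            pixel_pitch = movie$pixel_pitch,
            class = c("sta", "array"))
}

#' Separate an STA into spatial and temporal components
#'
#' Singular-value decomposition of the `lags x pixels` unfolding of the
#' STA; the leading singular triple gives a unit-norm temporal filter and
#' a unit-norm spatial receptive field. Signs are chosen so that the
#' spatial factor's peak-magnitude pixel is positive; the temporal factor
#' then carries the cell's polarity (OFF cells get a negative temporal
#' peak).
#'
#' @param sta an `sta` from [compute_sta()].
#' @return A list with `spatial` (matrix, class `spatial_rf`, unit
#'   Euclidean norm, attribute `pixel_pitch`), `temporal` (numeric vector,
#'   class `temporal_filter`, unit norm, attribute `frame_rate`), and
#'   `singular_values`.
#' @export
separate_sta <- function(sta) {
  d <- dim(sta)
  if (all(sta == 0)) stop("cannot factorize an all-zero STA", call. = FALSE)
  if (any(!is.finite(sta))) stop("STA contains non-finite values", call. = FALSE)
  U <- matrix(sta, d[1], d[2] * d[3])
  sv <- svd(U)
  temporal <- sv$u[, 1]
  spatial <- matrix(sv$v[, 1], d[2], d[3])
  if (spatial[which.max(abs(spatial))] < 0) {
    spatial <- -spatial
    temporal <- -temporal
  }
  structure(list(
    spatial = structure(spatial,
                        pixel_pitch = attr(sta, "pixel_pitch"),
                        class = c("spatial_rf", "matrix", "array")),
    temporal = structure(temporal,
                         frame_rate = attr(sta, "frame_rate"),
                         class = "temporal_filter"),
    singular_values = sv$d
  ), class = "sta_factors")
}
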