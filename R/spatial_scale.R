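#' Smoothing-scale sweep of the SC model
#'
#' Refits the SC model with the local spatial contrast computed from
#' progressively smoothed images (I_mean always comes from the original
#' images), and evaluates each fit on a held-out test split. The LN
#' baseline is fit once, since I_mean does not change with smoothing.
#' After the first scale, each SC fit is warm-started from the previous
#' scale's solution in addition to its random restarts.
#'
#' @param images list of [contrast_image]s.
#' @param rf a [gaussian_rf].
#' @param counts a [response_table] or numeric vector of trial-averaged
#'   counts per image.
#' @param scales increasing numeric vector of smoothing scales in
#'   micrometers; include 0 (no smoothing) to anchor the normalized
#'   improvement. Default `c(0, 15, 30, ..., 195)`.
#' @param polarity cell polarity forwarded to [feature_table()]
#'   (`"OFF"` flips the sign of the I_mean drive).
#' @param train_fraction training fraction of the image split.
#' @param restarts random restarts per SC fit (default 10; the warm start
#'   makes small values effective here).
#' @param seed integer seed controlling the split and the fits.
#' @return A `scale_curve` data.frame with columns `scale_um`, `r2`,
#'   `improvement` (`r2 / r2_ln`), `normalized_improvement`
#'   (improvement / improvement at scale 0), `w`, `ok`; attributes
#'   `r2_ln` and `n_test`.
#' @export
scale_sweep <- function(images, rf, counts, scales = seq(0, 195, by = 15),
                        polarity = c("ON", "OFF"),
                        train_fraction = 0.5, restarts = 10, seed = NULL) {
  polarity <- match.arg(polarity)
  if (is.unsorted(scales, strictly = TRUE))
    stop("`scales` must be strictly increasing", call. = FALSE)
  if (any(scales < 0)) stop("scales must be >= 0", call. = FALSE)
  mean_counts <- if (inherits(counts, "response_table"))
    rowMeans(counts) else as.numeric(counts)
  stopifnot(length(mean_counts) == length(images))
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  split <- split_train_test(length(images), train_fraction,
                            seed = derive_seed(seed, "split"))
  f0 <- feature_table(images, rf, smoothing_scale = 0, polarity = polarity)
  ln <- fit_ln(f0$i_mean[split$train], mean_counts[split$train],
               restarts = max(restarts, 20),
               seed = derive_seed(seed, "ln"))
  ev_ln <- evaluate_predictions(predict(ln, f0[split$test, ]),
                                mean_counts[split$test])
  rows <- vector("list", length(scales))
  warm <- NULL
  for (i in seq_along(scales)) {
    sc_um <- scales[i]
    res <- tryCatch({
      ft <- feature_table(images, rf, smoothing_scale = sc_um, polarity = polarity)
      fit <- fit_sc_warm(ft$i_mean[split$train], ft$lsc[split$train],
                         mean_counts[split$train], warm = warm,
                         restarts = restarts,
                         seed = derive_seed(seed, paste0("sc", i)))
      warm <<- fit
      ev <- evaluate_predictions(predict(fit, ft[split$test, ]),
                                 mean_counts[split$test])
      data.frame(scale_um = sc_um, r2 = ev$r2,
                 improvement = ev$r2 / ev_ln$r2,
                 w = fit$w, ok = TRUE)
    }, error = function(e) {
      warning(sprintf("scale %g um failed: %s", sc_um, conditionMessage(e)),
              call. = FALSE)
      data.frame(scale_um = sc_um, r2 = NA_real_, improvement = NA_real_,
                 w = NA_real_, ok = FALSE)
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  base <- out$improvement[out$scale_um == 0]
  out$normalized_improvement <-
    if (length(base) == 1 && is.finite(base)) out$improvement / base
    else NA_real_
  attr(out, "r2_ln") <- ev_ln$r2
  attr(out, "n_test") <- ev_ln$n_test
  class(out) <- c("scale_curve", "data.frame")
  out
}

# fit_sc plus an optional warm start taken as the first candidate.
fit_sc_warm <- function(i_mean, lsc, counts, warm = NULL, restarts = 10,
                        seed = NULL) {
  fit <- fit_sc(i_mean, lsc, counts, restarts = restarts, seed = seed)
  if (!is.null(warm) && sd(lsc) > 0) {
    wobj <- sum((softplus(i_mean + warm$w * lsc, warm$a1, warm$a2, warm$a3)
                 - counts)^2)
    if (wobj < fit$residual) {
      # polish the nonlinearity around the warm solution at fixed w
      th <- c(log(warm$a1), log(warm$a2), warm$a3)
      f2 <- fit_nonlinearity(th, i_mean + warm$w * lsc, counts)
      if (f2$value < fit$residual) {
        fit$a1 <- exp(f2$par[1]); fit$a2 <- exp(f2$par[2])
        fit$a3 <- f2$par[3]; fit$w <- warm$w
        fit$residual <- f2$value
      }
    }
  }
  fit
}

#' Optimal smoothing scale from a scale curve
#'
#' Locates the grid point with maximal r-squared and interpolates with a
#' second-order polynomial through that point and its two neighbors; the
#' parabola vertex is returned when it is a proper interior maximum
#' (negative curvature, vertex inside the neighbor interval). When the
#' maximum sits on the grid boundary, the boundary scale is returned and
#' flagged (no extrapolation beyond the grid).
#'
#' @param curve a `scale_curve` from [scale_sweep()], or any data.frame
#'   with columns `scale_um` and `r2`.
#' @return List with `optimal_scale_um`, `boundary` (logical), and the
#'   interpolating `coefficients` (c0, c1, c2) when interpolation was
#'   used.
#' @export
optimal_scale <- function(curve) {
  stopifnot(all(c("scale_um", "r2") %in% names(curve)))
  ok <- is.finite(curve$r2)
  x <- curve$scale_um[ok]; y <- curve$r2[ok]
  if (length(x) < 3)
    stop("need at least 3 finite points on the scale curve", call. = FALSE)
  i <- which.max(y)
  if (i == 1 || i == length(x)) {
    return(list(optimal_scale_um = x[i], boundary = TRUE,
                coefficients = NULL))
  }
  xs <- x[(i - 1):(i + 1)]; ys <- y[(i - 1):(i + 1)]
  cf <- solve(cbind(1, xs, xs^2), ys)   # exact quadratic through 3 points
  vertex <- -cf[2] / (2 * cf[3])
  if (cf[3] < 0 && vertex >= xs[1] && vertex <= xs[3]) {
    list(optimal_scale_um = unname(vertex), boundary = FALSE,
         coefficients = unname(cf))
  } else {
    list(optimal_scale_um = x[i], boundary = FALSE, coefficients = unname(cf))
  }
}

#' @export
plot.scale_curve <- function(x, ...) {
  graphics::plot(x$scale_um, x$improvement, type = "b", pch = 16,
                 xlab = "smoothing scale (um)",
                 ylab = expression(R^2 ~ "improvement over LN"), ...)
  opt <- tryCatch(optimal_scale(x), error = function(e) NULL)
  if (!is.null(opt)) graphics::abline(v = opt$optimal_scale_um, lty = 2)
  invisible(x)
}
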