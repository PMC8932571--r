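#' Softplus output nonlinearity
#'
#' `r(F) = a1 * ln(1 + exp(a2 * (F + a3)))`, evaluated overflow-safely.
#' `a1` sets the rate scale, `a2` the gain, `a3` an offset in drive
#' (contrast) units; `r(-a3) = a1 * ln 2` exactly.
#'
#' @param F numeric drive (scalar or vector).
#' @param a1,a2,a3 softplus parameters.
#' @return Nonnegative rates, same length as `F`.
#' @export
softplus <- function(F, a1, a2, a3) {
  z <- a2 * (F + a3)
  a1 * (pmax(z, 0) + log1p(exp(-abs(z))))
}

# Sum-of-squares objective for the softplus nonlinearity on drive F.
# theta = (log a1, log a2, a3); a1, a2 > 0 by construction, which keeps
# the nonlinearity monotone increasing in the drive.
softplus_sse <- function(theta, F, y) {
  r <- softplus(F, exp(theta[1]), exp(theta[2]), theta[3])
  v <- sum((r - y)^2)
  if (!is.finite(v)) 1e300 else v
}

# One Nelder-Mead pass for (a1, a2, a3) given drive F, from start theta.
fit_nonlinearity <- function(theta, F, y, maxit = 500) {
  optim(theta, softplus_sse, F = F, y = y, method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = 1e-10))
}

# Random data-scaled starting values for (log a1, log a2, a3).
random_start <- function(F, y) {
  sF <- sd(F)
  if (sF == 0) sF <- 1
  c(log(max(max(y), 0.5) * runif(1, 0.3, 1.5)),
    log(runif(1, 0.5, 4) / sF),
    -median(F) + rnorm(1, 0, sF))
}

new_encoding_model <- function(class, a1, a2, a3, w = NULL, residual,
                               n_train, restarts, converged, flags = character()) {
  structure(list(a1 = a1, a2 = a2, a3 = a3, w = w, residual = residual,
                 n_train = n_train, restarts = restarts,
                 converged = converged, flags = flags),
            class = c(class, "encoding_model"))
}

#' Fit the classical LN model nonlinearity
#'
#' Least-squares fit of the softplus nonlinearity to the relation between
#' the linear drive `F_LN = I_mean` and the trial-averaged spike count,
#' using derivative-free simplex search from multiple random data-scaled
#' starting points (best of restarts kept). `a1` and `a2` are kept
#' positive through a log parameterization, so the fitted nonlinearity is
#' monotone increasing; OFF cells are handled upstream by the sign
#' convention of the drive.
#'
#' @param i_mean numeric vector of linear drives (one per image).
#' @param counts numeric vector of trial-averaged spike counts.
#' @param restarts number of random restarts (default 50).
#' @param seed integer seed for the restart draws.
#' @return An object of class `c("ln_model", "encoding_model")` with
#'   elements `a1`, `a2`, `a3`, `residual`, `converged`, `flags`.
#' @export
fit_ln <- function(i_mean, counts, restarts = 50, seed = NULL) {
  stopifnot(length(i_mean) == length(counts))
  if (length(i_mean) < 4)
    stop("need at least 4 training points", call. = FALSE)
  if (sd(i_mean) == 0)
    stop("`i_mean` is constant; nonlinearity not identifiable", call. = FALSE)
  flags <- character()
  if (all(counts == 0)) flags <- c(flags, "degenerate: all-zero counts")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      th0 <- if (r == 1)
        c(log(max(max(counts), 0.5)), log(2 / max(sd(i_mean), 1e-12)),
          -median(i_mean))
      else random_start(i_mean, counts)
      fit <- fit_nonlinearity(th0, i_mean, counts)
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    best <- fit_nonlinearity(best$par, i_mean, counts, maxit = 2000)
    new_encoding_model("ln_model",
                       a1 = exp(best$par[1]), a2 = exp(best$par[2]),
                       a3 = best$par[3], residual = best$value,
                       n_train = length(counts), restarts = restarts,
                       converged = best$convergence == 0, flags = flags)
  })
}

#' Fit the spatial-contrast (SC) model
#'
#' The SC model drives the softplus nonlinearity with
#' `F_SC = I_mean + w * LSC`, adding a single free weight `w` for the
#' local spatial contrast. Fitting alternates least-squares optimization
#' of the nonlinearity `(a1, a2, a3)` at fixed `w` with one-dimensional
#' least-squares optimization of `w` at fixed nonlinearity, until the
#' relative residual change falls below `tol` (or `max_alternations` is
#' reached). The alternation is repeated from `restarts` random starting
#' values of `w` and of the nonlinearity, and the solution with the
#' smallest residual is kept.
#'
#' If `lsc` is constant, `w` is not identifiable: the fit falls back to
#' the LN solution with `w = 0` and is flagged.
#'
#' @param i_mean,lsc numeric vectors of per-image mean intensity and
#'   local spatial contrast.
#' @param counts numeric vector of trial-averaged spike counts.
#' @param restarts number of random restarts (default 200, a few hundred;
#'   reduce for speed in large sweeps).
#' @param max_alternations maximum outer alternations per restart
#'   (default 500).
#' @param tol relative residual-change convergence tolerance.
#' @param seed integer seed.
#' @return An object of class `c("sc_model", "encoding_model")`; as
#'   [fit_ln()] plus `w`, with attribute `residual_path` (per-alternation
#'   residuals of the winning restart; non-increasing).
#' @export
fit_sc <- function(i_mean, lsc, counts, restarts = 200,
                   max_alternations = 500, tol = 1e-8, seed = NULL) {
  stopifnot(length(i_mean) == length(counts), length(lsc) == length(counts))
  if (length(i_mean) < 5)
    stop("need at least 5 training points", call. = FALSE)
  if (sd(i_mean) == 0)
    stop("`i_mean` is constant; nonlinearity not identifiable", call. = FALSE)
  if (sd(lsc) == 0) {
    ln <- fit_ln(i_mean, counts, restarts = max(restarts, 10), seed = seed)
    out <- new_encoding_model("sc_model", ln$a1, ln$a2, ln$a3, w = 0,
                              residual = ln$residual, n_train = ln$n_train,
                              restarts = ln$restarts, converged = ln$converged,
                              flags = c(ln$flags, "w not identifiable: constant LSC"))
    attr(out, "residual_path") <- ln$residual
    return(out)
  }
  flags <- character()
  if (all(counts == 0)) flags <- c(flags, "degenerate: all-zero counts")

  sse_at <- function(theta, w)
    softplus_sse(theta, i_mean + w * lsc, counts)

  run_restart <- function(theta0, w0) {
    w <- w0
    fit <- fit_nonlinearity(theta0, i_mean + w * lsc, counts)
    path <- fit$value
    prev <- NULL
    for (it in seq_len(max_alternations)) {
      # (ii) optimize w at fixed nonlinearity
      a1 <- exp(fit$par[1]); a2 <- exp(fit$par[2]); a3 <- fit$par[3]
      wobj <- function(wv) {
        v <- sum((softplus(i_mean + wv * lsc, a1, a2, a3) - counts)^2)
        if (!is.finite(v)) 1e300 else v
      }
      span <- 5 * (1 + abs(w))
      wopt <- optim(w, wobj, method = "Brent",
                    lower = w - span, upper = w + span)
      w <- wopt$par
      # (i) optimize the nonlinearity at fixed w
      fit <- fit_nonlinearity(fit$par, i_mean + w * lsc, counts)
      # pattern move: w and the offset a3 trade off along a narrow
      # valley, so the alternation drifts in a stable direction; an
      # extrapolated step along that direction is accepted only when it
      # lowers the residual, preserving monotonicity.
      cur <- c(fit$par, w)
      if (!is.null(prev)) {
        dir <- cur - prev
        best_val <- fit$value
        best_p <- NULL
        for (s in c(2, 4, 8, 16)) {
          cand <- cur + s * dir
          v <- sse_at(cand[1:3], cand[4])
          if (is.finite(v) && v < best_val) { best_val <- v; best_p <- cand }
        }
        if (!is.null(best_p)) {
          f2 <- fit_nonlinearity(best_p[1:3], i_mean + best_p[4] * lsc, counts)
          if (f2$value < fit$value) {
            fit <- f2
            w <- best_p[4]
            cur <- c(fit$par, w)
          }
        }
      }
      path <- c(path, fit$value)
      n <- length(path)
      if (abs(path[n - 1] - path[n]) <= tol * max(path[n - 1], 1e-12)) break
      if (!is.null(prev) && max(abs(cur - prev)) < 1e-6) break
      prev <- cur
    }
    list(par = fit$par, w = w, value = fit$value, path = path,
         converged = fit$convergence == 0)
  }

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      th0 <- if (r == 1)
        c(log(max(max(counts), 0.5)), log(2 / max(sd(i_mean), 1e-12)),
          -median(i_mean))
      else random_start(i_mean, counts)
      w0 <- if (r == 1) 0 else runif(1, -2, 2)
      res <- run_restart(th0, w0)
      if (is.null(best) || res$value < best$value) best <- res
    }
    out <- new_encoding_model("sc_model",
                              a1 = exp(best$par[1]), a2 = exp(best$par[2]),
                              a3 = best$par[3], w = best$w,
                              residual = best$value,
                              n_train = length(counts), restarts = restarts,
                              converged = best$converged, flags = flags)
    attr(out, "residual_path") <- best$path
    out
  })
}

#' @export
print.encoding_model <- function(x, ...) {
  kind <- if (inherits(x, "sc_model")) "SC" else "LN"
  cat(sprintf("<%s model> a1 = %.4g, a2 = %.4g, a3 = %.4g%s\n", kind,
              x$a1, x$a2, x$a3,
              if (!is.null(x$w)) sprintf(", w = %.4g", x$w) else ""))
  cat(sprintf("  residual SSE %.4g on %d training images (%d restarts)\n",
              x$residual, x$n_train, x$restarts))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.encoding_model <- function(object, ...) {
  out <- c(a1 = object$a1, a2 = object$a2, a3 = object$a3)
  if (!is.null(object$w)) out <- c(out, w = object$w)
  out
}

#' Predict spike counts from a fitted encoding model
#'
#' @param object a fitted `ln_model` or `sc_model`.
#' @param newdata a data.frame with column `i_mean` (and `lsc` for the SC
#'   model), e.g. from [feature_table()].
#' @param ... unused.
#' @return Numeric vector of predicted mean spike counts.
#' @export
predict.ln_model <- function(object, newdata, ...) {
  softplus(newdata$i_mean, object$a1, object$a2, object$a3)
}

#' @rdname predict.ln_model
#' @export
predict.sc_model <- function(object, newdata, ...) {
  if (is.null(newdata$lsc))
    stop("SC-model prediction needs an `lsc` column", call. = FALSE)
  softplus(newdata$i_mean + object$w * newdata$lsc,
           object$a1, object$a2, object$a3)
}

#' Evaluate predictions by squared Pearson correlation
#'
#' Model performance is the squared correlation coefficient between
#' predicted and observed mean spike counts on held-out images (note this
#' is affine-invariant, unlike 1 - SSE/SST).
#'
#' @param pred,observed numeric vectors of equal length (>= 3).
#' @return A list with `r`, `r2`, `n_test`.
#' @export
evaluate_predictions <- function(pred, observed) {
  stopifnot(length(pred) == length(observed))
  if (length(pred) < 3) stop("need at least 3 test points", call. = FALSE)
  if (sd(observed) == 0 || sd(pred) == 0)
    stop("correlation undefined: constant prediction or observation vector",
         call. = FALSE)
  r <- cor(pred, observed)
  list(r = r, r2 = r^2, n_test = length(pred))
}

#' Prediction improvement of the SC over the LN model
#'
#' @param r2_sc,r2_ln squared correlations of the two models on the same
#'   test set.
#' @return The ratio `r2_sc / r2_ln`.
#' @export
prediction_improvement <- function(r2_sc, r2_ln) {
  if (r2_ln <= 0) return(NA_real_)
  r2_sc / r2_ln
}

#' Split images into training and test sets
#'
#' Random disjoint, exhaustive split (default 50/50, e.g. 300 images into
#' 150 training and 150 held-out test images).
#'
#' @param n_images number of images (or a vector of ids).
#' @param fraction training fraction (default 0.5).
#' @param seed integer seed.
#' @return List with integer vectors `train` and `test`.
#' @export
split_train_test <- function(n_images, fraction = 0.5, seed = NULL) {
  ids <- if (length(n_images) == 1) seq_len(n_images) else n_images
  if (length(ids) < 2) stop("need at least 2 images to split", call. = FALSE)
  n_train <- round(length(ids) * fraction)
  n_train <- min(max(n_train, 1), length(ids) - 1)
  with_seed(seed, {
    train <- sort(sample(ids, n_train))
    list(train = train, test = setdiff(ids, train))
  })
}
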