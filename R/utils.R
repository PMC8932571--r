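# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded at `seed`.
# seed = NULL leaves the current RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic per-stage seed derived from a master seed and a label,
# kept inside the 32-bit integer range.
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(master) * 7919 + h) %% .Machine$integer.max)
}

# Pearson correlation that turns the degenerate (zero-variance) case into
# an explicit NA with a warning instead of cor()'s NA + warning soup.
safe_cor <- function(x, y, label = "correlation") {
  if (sd(x) == 0 || sd(y) == 0) {
    warning(sprintf("%s undefined: constant input vector", label), call. = FALSE)
    return(NA_real_)
  }
  cor(x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}
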