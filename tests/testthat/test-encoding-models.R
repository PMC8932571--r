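test_that("softplus evaluates exactly and is overflow-safe", {
  expect_equal(softplus(-0.7, 2.5, 13, 0.7), 2.5 * log(2))
  expect_equal(softplus(0, 1, 1, 0), log(2))
  expect_lt(softplus(-50, 1, 1, 0), 1e-20)
  expect_equal(softplus(1000, 1, 1, 0), 1000)       # linear asymptote
  expect_equal(softplus(c(0, 1), 2, 3, 0),
               2 * log1p(exp(3 * c(0, 1))))
})

test_that("LN fits recover noiseless softplus data", {
  set.seed(40)
  F <- sort(runif(120, -0.4, 0.4))
  y <- softplus(F, 2, 8, 0.1)
  fit <- fit_ln(F, y, restarts = 10, seed = 41)
  pred <- predict(fit, data.frame(i_mean = F))
  expect_lt(sqrt(mean((pred - y)^2)), 1e-3)
  # monotone nondecreasing predictions under a2 > 0
  expect_true(all(diff(pred) >= 0))
  expect_gt(fit$a1, 0); expect_gt(fit$a2, 0)
})

test_that("LN fit degenerate inputs are flagged or rejected", {
  F <- seq(-1, 1, length.out = 20)
  z <- fit_ln(F, rep(0, 20), restarts = 3, seed = 1)
  expect_true(any(grepl("degenerate", z$flags)))
  expect_lt(max(predict(z, data.frame(i_mean = F))), 0.01)
  expect_error(fit_ln(rep(0.3, 10), 1:10), "constant")
  expect_error(fit_ln(1:3, 1:3), "4 training points")
})

test_that("SC fits recover the spatial-contrast weight from noiseless data", {
  set.seed(42)
  n <- 150
  i_mean <- runif(n, -0.3, 0.3)
  lsc <- runif(n, 0.05, 0.35)
  w_true <- 0.8
  y <- softplus(i_mean + w_true * lsc, 2, 8, 0.1)
  fit <- fit_sc(i_mean, lsc, y, restarts = 10, seed = 43)
  expect_lt(abs(fit$w - w_true), 0.05)
  pred <- predict(fit, data.frame(i_mean = i_mean, lsc = lsc))
  expect_lt(sqrt(mean((pred - y)^2)), 1e-3)
})

test_that("SC fits on LN-generated data stay at the null", {
  set.seed(44)
  n <- 200
  i_mean <- runif(n, -0.3, 0.3)
  lsc <- runif(n, 0.05, 0.35)                      # independent of the drive
  y <- softplus(i_mean, 2, 8, 0.1)
  sp <- split_train_test(n, seed = 45)
  ln <- fit_ln(i_mean[sp$train], y[sp$train], restarts = 10, seed = 46)
  sc <- fit_sc(i_mean[sp$train], lsc[sp$train], y[sp$train],
               restarts = 10, seed = 46)
  expect_lt(abs(sc$w) * sd(lsc), 0.05 * sd(i_mean))
  nd <- data.frame(i_mean = i_mean[sp$test], lsc = lsc[sp$test])
  r2_ln <- evaluate_predictions(predict(ln, nd), y[sp$test])$r2
  r2_sc <- evaluate_predictions(predict(sc, nd), y[sp$test])$r2
  expect_gt(r2_sc / r2_ln, 0.95)
  expect_lt(r2_sc / r2_ln, 1.05)
})

test_that("constant LSC degenerates to the LN solution with a flag", {
  set.seed(47)
  F <- runif(60, -0.3, 0.3)
  y <- softplus(F, 2, 8, 0.1)
  sc <- fit_sc(F, rep(0.2, 60), y, restarts = 5, seed = 48)
  expect_equal(sc$w, 0)
  expect_true(any(grepl("identifiable", sc$flags)))
  ln <- fit_ln(F, y, restarts = max(5, 10), seed = 48)
  expect_equal(predict(sc, data.frame(i_mean = F, lsc = rep(0.2, 60))),
               predict(ln, data.frame(i_mean = F)), tolerance = 1e-6)
})

test_that("the alternating objective never increases and restarts only help", {
  set.seed(49)
  n <- 100
  i_mean <- runif(n, -0.3, 0.3)
  lsc <- 0.2 + 0.3 * abs(i_mean) + runif(n, 0, 0.1)
  y <- softplus(i_mean + 0.5 * lsc, 2, 8, 0) + rnorm(n, 0, 0.1)
  fit <- fit_sc(i_mean, lsc, y, restarts = 4, seed = 50)
  path <- attr(fit, "residual_path")
  expect_true(all(diff(path) <= 1e-9))
  few <- fit_sc(i_mean, lsc, y, restarts = 2, seed = 51)
  many <- fit_sc(i_mean, lsc, y, restarts = 8, seed = 51)
  expect_lte(many$residual, few$residual + 1e-9)
})

test_that("prediction dispatch matches the scalar softplus and the w = 0 identity", {
  m <- structure(list(a1 = 2, a2 = 8, a3 = 0.1, w = 0),
                 class = c("sc_model", "encoding_model"))
  ln <- structure(list(a1 = 2, a2 = 8, a3 = 0.1),
                  class = c("ln_model", "encoding_model"))
  nd <- data.frame(i_mean = c(-0.2, 0, 0.3), lsc = c(0.1, 0.2, 0.3))
  expect_equal(predict(m, nd), predict(ln, nd))
  expect_equal(predict(ln, nd), softplus(nd$i_mean, 2, 8, 0.1))
  expect_error(predict(m, data.frame(i_mean = 1)), "lsc")
})

test_that("evaluation is squared Pearson correlation with its documented properties", {
  obs <- c(1, 3, 2, 5, 4, 6)
  expect_equal(evaluate_predictions(obs, obs)$r2, 1)
  expect_equal(evaluate_predictions(3 + 2 * obs, obs)$r2, 1)  # affine-invariant
  pred <- c(1, -1, 1, -1, 1, -1)
  obs0 <- c(1, 1, -1, -1, 1, 1)   # constructed zero covariance
  expect_equal(evaluate_predictions(pred, obs0)$r2, 0, tolerance = 1e-12)
  expect_error(evaluate_predictions(rep(1, 5), obs[1:5]), "constant")
  expect_error(evaluate_predictions(1:2, 2:1), "3 test points")
  expect_true(is.na(prediction_improvement(0.5, 0)))
})

test_that("train/test splits are disjoint, exhaustive, and seeded", {
  s <- split_train_test(300, seed = 52)
  expect_length(s$train, 150)
  expect_length(s$test, 150)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), 1:300)
  expect_identical(split_train_test(300, seed = 52), s)
  s2 <- split_train_test(2, seed = 53)
  expect_length(s2$train, 1); expect_length(s2$test, 1)
})
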