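test_that("contour masks have the analytic area, nest, and cover the grid in the limit", {
  rf <- gaussian_rf(c(31.5, 31.5), diag(25, 2))   # sigma = 5 px
  m3 <- contour_mask(rf, 3, dim = c(64, 64))
  area <- pi * 15^2
  # discretization error is at most on the order of the perimeter
  expect_lt(abs(attr(m3, "N") - area), 2 * pi * 15 + 10)
  m2 <- contour_mask(rf, 2, dim = c(64, 64))
  expect_true(all(m3[m2]))                        # nested
  m_inf <- contour_mask(rf, 1e6, dim = c(64, 64))
  expect_equal(attr(m_inf, "N"), 64 * 64)
  expect_error(contour_mask(rf, 0, dim = c(64, 64)), "positive")
})

test_that("effective diameter follows the full-axis 1.5-sigma convention", {
  expect_equal(effective_diameter(gaussian_rf(c(0, 0), diag(9, 2),
                                              pixel_pitch = 10)), 90)
  # sigma_x = 4, sigma_y = 1 px at 7.5 um pitch: 3 * sqrt(4 * 1) * 7.5
  expect_equal(effective_diameter(gaussian_rf(c(0, 0), diag(c(16, 1)),
                                              pixel_pitch = 7.5)), 45)
  # rotation leaves the diameter unchanged
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- R %*% diag(c(16, 1)) %*% t(R)
  expect_equal(effective_diameter(gaussian_rf(c(0, 0), S, pixel_pitch = 7.5)),
               45, tolerance = 1e-9)
})

test_that("STA factorization recovers exact rank-1 structure up to sign", {
  set.seed(20)
  tt <- biphasic_temporal_filter(10, 30)
  sp <- rf_weights(fixture_rf(sigma_px = 2, size_px = 9), c(9, 9))
  sp <- sp / sqrt(sum(sp^2))
  sta <- structure(outer(-tt, sp), class = c("sta", "array"),
                   pixel_pitch = 7.5, frame_rate = 30)
  fac <- separate_sta(sta)
  expect_equal(sqrt(sum(fac$spatial^2)), 1, tolerance = 1e-9)
  expect_equal(sqrt(sum(fac$temporal^2)), 1, tolerance = 1e-9)
  # spatial peak positive by convention; temporal carries the OFF sign
  expect_gt(fac$spatial[which.max(abs(fac$spatial))], 0)
  expect_equal(as.numeric(fac$temporal), as.numeric(-tt), tolerance = 1e-10)
  expect_equal(matrix(fac$spatial, 9, 9), sp, tolerance = 1e-10)
  resid <- sta - fac$singular_values[1] * outer(as.numeric(fac$temporal),
                                                unclass(fac$spatial))
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("STA factorization equals the best rank-1 approximation on random stacks", {
  set.seed(21)
  for (i in 1:3) {
    arr <- array(rnorm(10 * 8 * 9), dim = c(10, 8, 9))
    sta <- structure(arr, class = c("sta", "array"),
                     pixel_pitch = 7.5, frame_rate = 30)
    fac <- separate_sta(sta)
    M <- matrix(arr, 10, 72)
    o <- oracle_rank1(M)
    expect_equal(abs(o$s), fac$singular_values[1], tolerance = 1e-6)
    expect_equal(abs(sum(o$u * fac$temporal)), 1, tolerance = 1e-6)
  }
  expect_error(separate_sta(structure(array(0, c(3, 3, 3)),
                                      class = c("sta", "array"))),
               "zero")
})

test_that("rank-2 stacks yield the leading singular pair", {
  set.seed(22)
  u1 <- rnorm(10); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- rnorm(10); u2 <- u2 - sum(u2 * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
  v1 <- rnorm(36); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- rnorm(36); v2 <- v2 - sum(v2 * v1) * v1; v2 <- v2 / sqrt(sum(v2^2))
  M <- 10 * outer(u1, v1) + 1 * outer(u2, v2)
  sta <- structure(array(M, dim = c(10, 6, 6)), class = c("sta", "array"),
                   pixel_pitch = 7.5, frame_rate = 30)
  fac <- separate_sta(sta)
  expect_equal(fac$singular_values[1:2], c(10, 1), tolerance = 1e-9)
  expect_equal(abs(sum(fac$temporal * u1)), 1, tolerance = 1e-9)
})

test_that("the STA picks out a deterministic trigger square at lag zero", {
  movie <- generate_checkerboard_noise(400, grid_px = 8, square_px = 1,
                                       seed = 23)
  trig <- c(3, 5)   # row, col
  on <- which(movie$frames[trig[1], trig[2], ] == 1)
  on <- on[on >= 20]
  spikes <- (on - 1) / movie$frame_rate + 1e-4
  sta <- compute_sta(movie, spikes, lag_window = 660)
  lag0 <- sta[1, , ]
  expect_equal(which.max(lag0), (trig[2] - 1) * 8 + trig[1])
  expect_equal(max(lag0), 1)
  expect_equal(attr(sta, "n_spikes"), length(spikes))
})

test_that("a single spike reproduces its stimulus segment; no qualifying spikes error", {
  movie <- generate_checkerboard_noise(60, grid_px = 4, square_px = 1,
                                       seed = 24)
  spike_frame <- 30
  spikes <- (spike_frame - 1) / 30 + 0.001
  sta <- compute_sta(movie, spikes, lag_window = 660)
  for (l in c(1, 7, 20))
    expect_equal(sta[l, , ], movie$frames[, , spike_frame - l + 1])
  expect_error(compute_sta(movie, c(0.05), lag_window = 660), "qualifying")
})

test_that("stimulus-independent spiking leaves only CLT-level STA structure", {
  movie <- generate_checkerboard_noise(3000, grid_px = 6, square_px = 1,
                                       seed = 25)
  set.seed(25)
  frames <- sample(20:3000, 2500)        # distinct frames: unit multiplicity
  spikes <- sort((frames - 1) / 30 + 0.001)
  sta <- compute_sta(movie, spikes, lag_window = 660)
  expect_lt(max(abs(sta)), 4 / sqrt(attr(sta, "n_spikes")))
})

test_that("Gaussian RF fits recover known parameters", {
  truth <- gaussian_rf(c(20, 12), diag(c(16, 4)), pixel_pitch = 7.5)
  z <- 0.8 * rf_weights(truth, c(28, 40)) + 0.05
  fit <- fit_gaussian_rf(z, pixel_pitch = 7.5)
  expect_lt(max(abs(fit$mu - truth$mu)), 0.05)
  expect_equal(diag(fit$sigma), diag(truth$sigma), tolerance = 0.01)
  expect_lt(abs(fit$sigma[1, 2]), 0.05)
  expect_equal(attr(fit, "amplitude"), 0.8, tolerance = 0.01)
  expect_equal(attr(fit, "offset"), 0.05, tolerance = 0.01)
  expect_true(attr(fit, "converged"))
  # additive noise at SNR 10: center within half a pixel
  set.seed(26)
  zn <- z + matrix(rnorm(length(z), 0, 0.08), nrow(z), ncol(z))
  fitn <- fit_gaussian_rf(zn, pixel_pitch = 7.5)
  expect_lt(sqrt(sum((fitn$mu - truth$mu)^2)), 0.5)
  expect_error(fit_gaussian_rf(matrix(1, 10, 10)), "constant")
})

test_that("fitted shape is invariant to uniform rescaling of the map", {
  truth <- gaussian_rf(c(10, 11), matrix(c(9, 2, 2, 6), 2, 2))
  z <- rf_weights(truth, c(24, 24))
  f1 <- fit_gaussian_rf(z)
  f2 <- fit_gaussian_rf(17.3 * z)
  expect_equal(f1$mu, f2$mu, tolerance = 1e-4)
  expect_equal(f1$sigma, f2$sigma, tolerance = 1e-3)
  expect_equal(effective_diameter(f1), effective_diameter(f2),
               tolerance = 1e-4)
})
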