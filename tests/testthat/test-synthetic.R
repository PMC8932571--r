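test_that("generated images are standardized, clipped, and seed-deterministic", {
  imgs <- generate_images(6, size_px = 32, spectral_exponent = 0,
                          contrast_inhomogeneity = 0, seed = 30)
  for (im in imgs) {
    expect_true(all(im >= -1 & im <= 1))
    # white-noise images at SD 0.5 lose ~5% of their SD to clipping at +-1
    expect_gt(sd(as.vector(im)), 0.45)
    expect_lt(sd(as.vector(im)), 0.51)
    expect_lt(abs(mean(im)), 0.02)
  }
  imgs2 <- generate_images(6, size_px = 32, spectral_exponent = 0,
                           contrast_inhomogeneity = 0, seed = 30)
  expect_identical(lapply(imgs, unclass), lapply(imgs2, unclass))
  expect_error(generate_images(1), "at least 2")
  expect_error(generate_images(10, size_px = 4), "at least 8")
  expect_error(generate_images(10, target_sd_fraction = 0), "0, 1")
})

test_that("checkerboard noise is binary, unbiased per square, and reproducible", {
  m <- generate_checkerboard_noise(1000, grid_px = 16, square_px = 4,
                                   seed = 31)
  expect_true(all(m$frames %in% c(-1, 1)))
  # squares expand correctly: constant within each 4x4 block
  f1 <- m$frames[, , 1]
  expect_true(all(f1[1:4, 1:4] == f1[1, 1]))
  # per-square mean over frames within a binomial CI (~4 / sqrt(n))
  sq_means <- apply(m$frames[seq(1, 16, 4), seq(1, 16, 4), ], c(1, 2), mean)
  expect_lt(max(abs(sq_means)), 4 / sqrt(1000))
  # full-field flicker in the degenerate case
  ff <- generate_checkerboard_noise(10, grid_px = 8, square_px = 8, seed = 31)
  expect_true(all(apply(ff$frames, 3, function(f) length(unique(as.vector(f)))) == 1))
  expect_identical(generate_checkerboard_noise(20, 8, 2, seed = 9)$frames,
                   generate_checkerboard_noise(20, 8, 2, seed = 9)$frames)
  expect_error(generate_checkerboard_noise(10, grid_px = 10, square_px = 3),
               "divisible")
})

test_that("flash responses follow the closed-form generative pipeline", {
  rf <- fixture_rf(sigma_px = 3, size_px = 24)
  cell <- synthetic_cell(rf, polarity = "OFF", kind = "linear",
                         response_heterogeneity = 0,
                         noise = noise_spec("deterministic"))
  img <- contrast_image(matrix(-0.5, 24, 24))
  tab <- simulate_flash_responses(cell, list(img, img), 3)
  # closed form: OFF drive = +0.5 * mean(G) over the 3-sigma mask
  k <- contour_mask(rf, 3, c(24, 24))
  G <- rf_weights(rf, c(24, 24))
  drive <- 0.5 * sum(G[k]) / attr(k, "N")
  lam <- softplus(drive, 3, 25, 0)
  expect_equal(as.vector(unclass(tab)), rep(round(lam), 6))
  expect_equal(attr(tab, "expected"), rep(lam, 2), tolerance = 1e-12)
  # zero contrast with a strongly negative offset: silent
  quiet <- synthetic_cell(rf, kind = "linear", response_heterogeneity = 0,
                          output_params = c(3, 25, -2),
                          noise = noise_spec("deterministic"))
  tab0 <- simulate_flash_responses(quiet,
                                   list(contrast_image(matrix(0, 24, 24)),
                                        contrast_image(matrix(0, 24, 24))), 2)
  expect_true(all(tab0 == 0))
  expect_error(simulate_flash_responses(cell, list(img, img), 0), "n_trials")
})

test_that("trial noise calibrates to the requested Fano factor", {
  rf <- fixture_rf(sigma_px = 3, size_px = 24)
  img <- contrast_image(matrix(-0.3, 24, 24))
  mk <- function(noise) {
    cell <- synthetic_cell(rf, polarity = "OFF", kind = "linear",
                           response_heterogeneity = 0, noise = noise)
    tab <- simulate_flash_responses(cell, list(img, img), 5000, seed = 32)
    ff <- fano_factors(tab)
    c(ff$cell, rowMeans(tab)[1])
  }
  sub <- mk(noise_spec("sub-poisson", target_fano = 0.3))
  expect_gt(sub[1], 0.25); expect_lt(sub[1], 0.35)
  poi <- mk(noise_spec("poisson"))
  expect_equal(poi[1], 1, tolerance = 0.05)
})

test_that("split-field reversal separates linear from subunit cells", {
  rf <- fixture_rf(sigma_px = 6, size_px = 48)
  half <- matrix(rep(c(-0.4, 0.4), each = 48 * 24), 48, 48)
  pair <- list(contrast_image(half), contrast_image(-half))
  inv_drive <- function(cell) {
    tab <- simulate_flash_responses(cell, pair, 1)
    a <- cell$output_params
    softplus_inv(attr(tab, "expected"), a[1], a[2], a[3])
  }
  lin <- synthetic_cell(rf, polarity = "OFF", kind = "linear",
                        response_heterogeneity = 0,
                        noise = noise_spec("deterministic"))
  d_lin <- inv_drive(lin)
  expect_equal(sum(d_lin), 0, tolerance = 1e-6)     # drives cancel
  sub <- synthetic_cell(rf, polarity = "OFF", kind = "subunit",
                        response_heterogeneity = 0,
                        noise = noise_spec("deterministic"))
  d_sub <- inv_drive(sub)
  expect_gt(sum(d_sub), 0.05)   # rectified subunits respond to both phases
})

test_that("white-noise spiking is silent at zero gain, sorted, in range, reproducible", {
  movie <- generate_checkerboard_noise(200, grid_px = 12, square_px = 1,
                                       seed = 33)
  rf <- gaussian_rf(c(5.5, 5.5), diag(4, 2), pixel_pitch = 30)
  mute <- synthetic_cell(rf, kind = "linear", output_params = c(0, 25, 0))
  expect_length(simulate_white_noise_spikes(mute, movie, seed = 34), 0)
  cell <- synthetic_cell(rf, polarity = "OFF", kind = "linear",
                         output_params = c(1.5, 25, 0))
  s1 <- simulate_white_noise_spikes(cell, movie, seed = 34)
  expect_false(is.unsorted(s1))
  expect_true(all(s1 >= 0 & s1 <= 200 / 30))
  s2 <- simulate_white_noise_spikes(cell, movie, seed = 34)
  expect_identical(s1, s2)
  short <- generate_checkerboard_noise(10, grid_px = 12, square_px = 1,
                                       seed = 35)
  expect_error(simulate_white_noise_spikes(cell, short), "shorter")
})

test_that("generator validation catches bad specifications", {
  rf <- fixture_rf()
  expect_error(synthetic_cell(rf, kind = "subunit", subunit_sigma = 0),
               "subunit_sigma")
  expect_error(synthetic_cell(rf, output_params = c(-1, 2, 0)), "a1")
  expect_error(noise_spec("sub-poisson", target_fano = 0), "0, 1")
  expect_error(noise_spec("sub-poisson", target_fano = 1.2), "0, 1")
})
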