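test_that("phantom geometry rasterises disks with the right area and rejects bad layouts", {
  spec1 <- phantom_spec(shape = c(64, 64),
                        compartments = list(
                          compartment(1, c(32, 32), 10, s0 = 900,
                                      adc = 1e-3)))
  lab <- build_phantom_geometry(spec1)
  expect_true(sum(lab == 1) >= 298 && sum(lab == 1) <= 330)  # pi*100 +- 5%
  expect_identical(dim(lab), c(64L, 64L))

  empty <- phantom_spec(shape = c(32, 32), compartments = list())
  expect_true(all(build_phantom_geometry(empty) == 0L))

  overlapping <- phantom_spec(shape = c(64, 64),
                              compartments = list(
                                compartment(1, c(30, 30), 4, 900, 1e-3),
                                compartment(2, c(30, 35), 4, 900, 1e-3)))
  expect_error(build_phantom_geometry(overlapping), "overlap")

  expect_error(
    phantom_spec(shape = c(64, 64),
                 compartments = list(compartment(1, c(5, 5), 10, 900, 1e-3))),
    "fit inside")
})

test_that("noiseless signal follows the mono-exponential decay", {
  spec <- phantom_spec(shape = c(40, 40),
                       compartments = list(
                         compartment(1, c(20, 20), 10, s0 = 925.93,
                                     adc = 1023.96e-6)))
  lab <- build_phantom_geometry(spec)
  img0 <- simulate_signal(lab, spec, 0)
  expect_equal(img0[20, 20], 925.93)  # exp(0) = 1
  img1000 <- simulate_signal(lab, spec, 1000)
  # the calibrated 40%-PVP decay reproduces the reference signal at b=1000
  expect_equal(img1000[20, 20], 332.54, tolerance = 2e-4)

  spec2 <- phantom_spec(shape = c(40, 40),
                        compartments = list(
                          compartment(1, c(20, 20), 10, s0 = 1000,
                                      adc = 1e-3)))
  lab2 <- build_phantom_geometry(spec2)
  expect_equal(simulate_signal(lab2, spec2, 1000)[20, 20], 1000 * exp(-1),
               tolerance = 1e-12)
})

test_that("log compartment means are affine in b for a noiseless series", {
  spec <- phantom_spec(shape = c(48, 48), noise_sigma = 0,
                       compartments = list(
                         compartment(1, c(24, 24), 12, s0 = 800,
                                     adc = 1.3e-3)))
  series <- generate_series(spec)
  lab <- series$labelmap
  means <- vapply(series$images, function(im) mean(im[lab == 1]), numeric(1))
  fit <- lm(log(means) ~ spec$bvalues)
  expect_lt(max(abs(residuals(fit))), 1e-12)
  expect_equal(unname(-coef(fit)[2]), 1.3e-3, tolerance = 1e-12)
})

test_that("Rician noise has the Rayleigh mean on zero signal and the Monte-Carlo mean on strong signal", {
  z <- matrix(0, 1000, 1000)
  noisy <- add_rician_noise(z, sigma = 1, seed = 11)
  expect_true(all(noisy >= 0))
  expect_equal(mean(noisy), sqrt(pi / 2), tolerance = 0.01 / 1.2533)

  # independent Monte-Carlo oracle for the Rician mean at s = 10, sigma = 1
  set.seed(99)
  nmc <- 2e6
  mc_mean <- mean(sqrt((10 + rnorm(nmc))^2 + rnorm(nmc)^2))
  s10 <- add_rician_noise(matrix(10, 1000, 1000), sigma = 1, seed = 12)
  expect_equal(mean(s10), mc_mean, tolerance = 0.01 / mc_mean)
  # and the high-SNR closed form sqrt(s^2 + sigma^2)
  expect_equal(mean(s10), sqrt(101), tolerance = 1e-3)

  img <- random_image(8, 8, seed = 3)
  expect_identical(add_rician_noise(img, 0), img)
  expect_error(add_rician_noise(img, -1), "sigma")
})

test_that("series generation is seed-deterministic and respects the b ladder", {
  spec <- default_phantom_spec(shape = c(96, 96), seed = 7)
  s1 <- generate_series(spec)
  s2 <- generate_series(spec)
  expect_identical(s1$images, s2$images)
  expect_length(s1$images, 11)
  expect_identical(s1$bvalues, seq(0, 2000, by = 200))

  s3 <- generate_series(default_phantom_spec(shape = c(96, 96), seed = 8))
  expect_false(identical(s1$images[[1]], s3$images[[1]]))
})

test_that("noiseless series recovers every compartment ADC to machine precision", {
  spec <- default_phantom_spec(shape = c(96, 96), noise_sigma = 0)
  series <- generate_series(spec)
  lab <- series$labelmap
  for (cp in spec$compartments) {
    means <- vapply(series$images, function(im) mean(im[lab == cp$label]),
                    numeric(1))
    est <- estimate_adc(means, series$bvalues, method = "pairwise_to_b0")
    expect_lt(max(abs(est$adc - cp$adc)) / cp$adc, 1e-12)
    est_ll <- estimate_adc(means, series$bvalues, method = "loglinear")
    expect_lt(abs(est_ll - cp$adc) / cp$adc, 1e-10)
  }
})

test_that("noise calibration hits the target SNR", {
  spec <- default_phantom_spec(shape = c(128, 128), seed = 5)
  sigma <- calibrate_noise_sigma(spec, snr_target = 97, b_target = 1000)
  lab <- build_phantom_geometry(spec)
  noisy <- add_rician_noise(simulate_signal(lab, spec, 1000), sigma,
                            seed = spec$seed)
  rois <- default_rois(spec)
  snr <- compute_snr(roi_stats(noisy, rois$signal),
                     roi_stats(noisy, rois$background))
  expect_equal(snr, 97, tolerance = 0.01)
  # the shipped default sigma was produced by this calibration
  expect_equal(default_phantom_spec()$noise_sigma, 3.43, tolerance = 0.15)
})
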