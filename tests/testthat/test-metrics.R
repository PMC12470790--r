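test_that("ROI statistics use the population SD and match a loop oracle", {
  const <- matrix(2.2, 30, 30)
  st <- roi_stats(const, roi_spec(c(3, 3), c(10, 10)))
  expect_equal(st$mean, 2.2)
  expect_equal(st$sd, 0)

  m <- matrix(c(1, 1, 3, 3), 2, 2)
  st2 <- roi_stats(m, roi_spec(c(1, 1), c(2, 2)))
  expect_equal(st2$mean, 2)
  expect_equal(st2$sd, 1)
  expect_equal(st2$n, 4L)

  img <- random_image(40, 40, seed = 13, lo = 0, hi = 300)
  st3 <- roi_stats(img, roi_spec(c(7, 9), c(25, 25)))
  want <- oracle_roi_stats(img, 7, 9, 25, 25)
  expect_lt(abs(st3$mean - want$mean), 1e-12 * want$mean)
  expect_lt(abs(st3$sd - want$sd), 1e-12)

  expect_error(roi_stats(img, roi_spec(c(30, 30), c(25, 25))), "outside")
})

test_that("SNR and CNR follow their ROI definitions", {
  expect_equal(compute_snr(c(100, 5), c(20, 2)), 50)
  expect_equal(compute_snr(c(0, 5), c(20, 2)), 0)
  expect_error(compute_snr(c(100, 5), c(20, 0)), "undefined")
  # reference sweep optimum row: mean 332.55, background SD 1.54
  expect_equal(compute_snr(c(332.55, 1.55), c(0, 1.54)), 215.94, tolerance = 1e-4)

  expect_equal(compute_cnr(c(10, 3), c(2, 4)), 8 / 5)
  expect_equal(compute_cnr(c(7, 1), c(7, 2)), 0)
  expect_error(compute_cnr(c(1, 0), c(2, 0)), "undefined")
  # antisymmetry and scale invariance
  s <- c(120, 4); b <- c(30, 3)
  expect_equal(compute_cnr(s, b), -compute_cnr(b, s))
  expect_equal(compute_cnr(3 * s, 3 * b), compute_cnr(s, b))
  expect_equal(compute_snr(3 * s, 3 * b), compute_snr(s, b))
})

test_that("scaling an image leaves measured SNR and CNR unchanged", {
  img <- random_image(40, 40, seed = 14, lo = 1, hi = 200)
  rois <- list(signal = roi_spec(c(3, 3), c(12, 12)),
               background = roi_spec(c(22, 22), c(12, 12),
                                     role = "background"))
  get <- function(im) {
    s <- roi_stats(im, rois$signal); b <- roi_stats(im, rois$background)
    c(compute_snr(s, b), compute_cnr(s, b))
  }
  expect_equal(get(img * 7.3), get(img), tolerance = 1e-12)
})

test_that("ADC estimation inverts mono-exponential decay and reproduces the reference range", {
  # reference decay pairs for the 40% PVP region
  expect_equal(estimate_adc(c(925.93, 759.45), c(0, 200))$adc, 991.02e-6,
               tolerance = 1e-5)
  expect_equal(estimate_adc(c(925.93, 332.54), c(0, 1000))$adc, 1024.04e-6,
               tolerance = 1e-5)

  b <- seq(0, 2000, 200)
  s <- 1000 * exp(-1e-3 * b)
  pw <- estimate_adc(s, b)
  expect_lt(max(abs(pw$adc - 1e-3)), 1e-15)
  expect_equal(estimate_adc(s, b, method = "loglinear"), 1e-3,
               tolerance = 1e-12)
  # loglinear equals pairwise exactly under exact decay
  expect_equal(estimate_adc(s, b, method = "loglinear"), pw$adc[1],
               tolerance = 1e-12)

  expect_error(estimate_adc(c(-1, 2), c(0, 100)), "positive")
  expect_error(estimate_adc(c(1, 2), c(100, 200)), "start at 0")
})

test_that("line profiles sample rows exactly and planes analytically", {
  img <- random_image(20, 20, seed = 15)
  pr <- line_profile(img, c(5, 1), c(5, 20))
  expect_equal(pr$value, img[5, ])
  expect_equal(pr$position, 0:19)

  single <- line_profile(img, c(4, 4), c(4, 4))
  expect_equal(nrow(single), 1L)
  expect_equal(single$value, img[4, 4])

  # bilinear interpolation reproduces an affine plane exactly
  plane <- outer(1:20, 1:20, function(r, c) 0.7 * r - 0.3 * c + 2)
  diag_pr <- line_profile(plane, c(2, 3), c(17, 15))
  want <- 0.7 * diag_pr$row - 0.3 * diag_pr$col + 2
  expect_lt(max(abs(diag_pr$value - want)), 1e-12)

  expect_error(line_profile(img, c(0, 1), c(5, 5)), "inside")
})

test_that("edge width measures the 10-90% rise and grows with blur", {
  step <- tibble::tibble(position = 0:9,
                         value = c(rep(0, 5), rep(1, 5)))
  expect_lte(edge_width(step), 1)

  ramp <- tibble::tibble(position = 0:10, value = seq(0, 1, by = 0.1))
  expect_equal(edge_width(ramp), 8, tolerance = 1e-12)

  # box-blurring a step widens the edge monotonically
  widths <- vapply(1:5, function(w) {
    x <- c(rep(0, 12), rep(1, 12))
    sm <- stats::filter(x, rep(1 / (2 * w + 1), 2 * w + 1), sides = 2)
    keep <- !is.na(sm)
    edge_width(tibble::tibble(position = seq_along(sm)[keep] - 1,
                              value = as.numeric(sm[keep])))
  }, numeric(1))
  expect_true(all(diff(widths) > 0))

  flat <- tibble::tibble(position = 0:20,
                         value = rep(c(0.5, 0.502), length.out = 21))
  expect_error(edge_width(flat), "transition")
})

test_that("CNR across b rises then falls with one interior maximum on the calibrated phantom", {
  spec <- default_phantom_spec(shape = c(128, 128), seed = 3)
  series <- generate_series(spec)
  scan <- bvalue_scan(series, default_rois(spec))
  cnr <- scan$cnr
  imax <- which.max(cnr)
  expect_gt(imax, 1)
  expect_lt(imax, length(cnr))
  expect_true(all(diff(cnr[1:imax]) > 0))
  expect_true(all(diff(cnr[imax:length(cnr)]) < 0))
})
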