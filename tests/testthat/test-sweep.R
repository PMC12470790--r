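test_that("the working b-value maximises CNR with ties toward smaller b", {
  ref <- reference_bvalue_table()
  expect_equal(select_working_bvalue(ref), 1000)

  falling <- tibble::tibble(bvalue = c(200, 400, 600), cnr = c(9, 5, 1))
  expect_equal(select_working_bvalue(falling), 200)

  tied <- tibble::tibble(bvalue = c(800, 1000), cnr = c(4, 4))
  expect_equal(select_working_bvalue(tied), 800)

  expect_error(select_working_bvalue(tibble::tibble(bvalue = numeric(),
                                                    cnr = numeric())),
               "empty")
})

test_that("b-value scan produces one consistent row per image", {
  spec <- default_phantom_spec(shape = c(96, 96), seed = 2)
  series <- generate_series(spec)
  rois <- default_rois(spec)
  scan <- bvalue_scan(series, rois)
  expect_equal(nrow(scan), 11L)
  expect_identical(scan$bvalue, series$bvalues)
  expect_true(all(is.finite(scan$snr)) && all(is.finite(scan$cnr)))
  # row 6 agrees with direct metric calls on the b = 1000 image
  s <- roi_stats(series$images[[6]], rois$signal)
  b <- roi_stats(series$images[[6]], rois$background)
  expect_equal(scan$snr[6], compute_snr(s, b))
  expect_equal(scan$cnr[6], compute_cnr(s, b))

  one <- list(images = series$images[6], bvalues = 1000)
  expect_equal(nrow(bvalue_scan(one, rois)), 1L)

  clean <- generate_series(default_phantom_spec(shape = c(96, 96),
                                                noise_sigma = 0))
  expect_error(bvalue_scan(clean, rois), "undefined")
})

test_that("the d grid is inclusive and a one-point sweep equals denoise + metrics", {
  expect_length(seq(sweep_config()$d_min, sweep_config()$d_max,
                    by = sweep_config()$d_step), 150)

  spec <- default_phantom_spec(shape = c(64, 64), seed = 4)
  series <- generate_series(spec)
  img <- series$images[[6]]
  rois <- default_rois(spec, size = 13L)
  cfg1 <- sweep_config(d_min = 0.02, d_max = 0.021, d_step = 0.01)
  sw <- sweep_smoothing_factor(img, rois, cfg1)
  expect_equal(nrow(sw), 1L)
  den <- nlm_denoise_fast(img, nlm_params(d = 0.02))
  s <- roi_stats(den, rois$signal); b <- roi_stats(den, rois$background)
  expect_equal(sw$snr, compute_snr(s, b), tolerance = 1e-12)
  expect_equal(sw$cnr, compute_cnr(s, b), tolerance = 1e-12)

  # rerunning yields the identical table (pure function)
  expect_identical(as.data.frame(sw),
                   as.data.frame(sweep_smoothing_factor(img, rois, cfg1)))
})

test_that("the plateau knee picks the first d reaching 95% of peak CNR", {
  ref <- reference_sweep_table()
  cfg <- sweep_config(plateau_fraction = 0.95)
  expect_equal(select_optimal_d(ref, cfg), 0.014)
  # the selected row carries the reference optimum metrics
  sel <- ref[ref$d == select_optimal_d(ref, cfg), ]
  expect_equal(sel$snr, 215.81)
  expect_equal(sel$cnr, 131.98)

  # constructed plateau starting at d = 0.010
  plateau <- tibble::tibble(d = seq(0.001, 0.02, by = 0.001))
  plateau$cnr <- ifelse(plateau$d < 0.010, 10 * plateau$d / 0.010, 10)
  expect_equal(select_optimal_d(plateau, cfg), 0.010)

  # monotone saturating curve: max_cnr picks the last d, the knee an
  # earlier crossing, never with higher CNR
  rising <- tibble::tibble(d = seq(0.001, 0.01, by = 0.001),
                           cnr = cumsum(c(5, 2, 1, 0.5, rep(0.1, 6))))
  d_knee <- select_optimal_d(rising, cfg)
  d_max <- select_optimal_d(rising, sweep_config(optimum_policy = "max_cnr"))
  expect_equal(d_max, 0.01)
  expect_lte(d_knee, d_max)
  expect_lte(rising$cnr[rising$d == d_knee][1],
             rising$cnr[rising$d == d_max][1])
})

test_that("fold changes truncate to two decimals and never round up", {
  expect_equal(fold_change(215.81, 96.87), 2.22)
  expect_equal(fold_change(131.98, 43.63), 3.02)
  expect_equal(fold_change(1, 1), 1)
  expect_equal(fold_change(131.98, 57.67), 2.28)  # 2.2889 truncates, not rounds
  expect_error(fold_change(1, 0), "denominator")

  set.seed(20)
  a <- runif(200, 0.1, 300); b <- runif(200, 0.1, 300)
  expect_true(all(fold_change(a, b) <= a / b + 1e-12))
  expect_true(all(fold_change(a, b) * fold_change(b, a) <= 1.0001))
})

test_that("the comparison study is deterministic and degenerate-flags noiseless input", {
  spec <- default_phantom_spec(shape = c(64, 64), seed = 6)
  series <- generate_series(spec)
  img <- series$images[[6]]
  rois <- default_rois(spec, size = 13L)
  cmp1 <- run_comparison_study(img, rois, nlm_d = 0.02)
  cmp2 <- run_comparison_study(img, rois, nlm_d = 0.02)
  expect_identical(cmp1$metrics, cmp2$metrics)
  expect_false(cmp1$degenerate)
  expect_equal(cmp1$metrics$method, c("none", "median", "wiener", "tv", "nlm"))
  expect_equal(cmp1$metrics$snr_fold[1], 1)
  expect_equal(nrow(cmp1$nlm_vs_baselines), 3L)

  clean <- generate_series(default_phantom_spec(shape = c(64, 64),
                                                noise_sigma = 0))
  cmp3 <- run_comparison_study(clean$images[[6]], rois, nlm_d = 0.02)
  expect_true(cmp3$degenerate)

  # profile output, one trace per method
  prof <- list(start = c(32, 2), end = c(32, 63))
  cmp4 <- run_comparison_study(img, rois, nlm_d = 0.02, profile = prof)
  expect_equal(sort(unique(cmp4$profiles$method)),
               sort(c("none", "median", "wiener", "tv", "nlm")))
})

test_that("tidy, glance and autoplot work on sweep and comparison objects", {
  spec <- default_phantom_spec(shape = c(64, 64), seed = 8)
  img <- generate_series(spec)$images[[6]]
  rois <- default_rois(spec, size = 13L)
  cfg <- sweep_config(d_min = 0.005, d_max = 0.05, d_step = 0.005)
  sw <- sweep_smoothing_factor(img, rois, cfg)
  td <- generics::tidy(sw)
  expect_identical(names(td), c("d", "metric", "value"))
  expect_equal(nrow(td), 2L * nrow(sw))
  gl <- generics::glance(sw, cfg)
  expect_equal(gl$n_d, 10L)
  expect_true(gl$d_opt %in% sw$d)
  expect_s3_class(ggplot2::autoplot(sw, cfg), "ggplot")

  cmp <- run_comparison_study(img, rois, nlm_d = gl$d_opt)
  expect_s3_class(generics::tidy(cmp), "tbl_df")
  expect_s3_class(generics::glance(cmp), "tbl_df")
  expect_s3_class(ggplot2::autoplot(cmp), "ggplot")
})
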