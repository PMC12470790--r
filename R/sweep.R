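#' Configuration of the smoothing-factor sweep
#'
#' @param d_min,d_max,d_step Inclusive grid of smoothing factors; the
#'   defaults 0.001-0.150 in steps of 0.001 give 150 settings.
#' @param plateau_fraction Fraction of the maximum CNR that defines the
#'   plateau for the knee rule (default 0.95).
#' @param optimum_policy `"plateau_knee"` (default): smallest d whose CNR
#'   reaches `plateau_fraction` of the sweep maximum — the codification of
#'   "steep rise, then plateau; pick the start of the plateau".
#'   `"max_cnr"`: the d maximizing CNR outright.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(d_min = 0.001, d_max = 0.150, d_step = 0.001,
                         plateau_fraction = 0.95,
                         optimum_policy = c("plateau_knee", "max_cnr")) {
  optimum_policy <- match.arg(optimum_policy)
  stopifnot(d_min > 0, d_max > d_min, d_step > 0,
            plateau_fraction > 0, plateau_fraction <= 1)
  structure(list(d_min = d_min, d_max = d_max, d_step = d_step,
                 plateau_fraction = plateau_fraction,
                 optimum_policy = optimum_policy),
            class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf("<sweep_config> d in [%g, %g] step %g; policy %s (plateau %g)\n",
              x$d_min, x$d_max, x$d_step, x$optimum_policy,
              x$plateau_fraction))
  invisible(x)
}

.roi_metrics <- function(img, rois) {
  s <- roi_stats(img, rois$signal)
  b <- roi_stats(img, rois$background)
  tibble::tibble(
    signal_mean = s$mean, signal_sd = s$sd,
    background_mean = b$mean, background_sd = b$sd,
    snr = tryCatch(compute_snr(s, b), error = function(e) NA_real_),
    cnr = tryCatch(compute_cnr(s, b), error = function(e) NA_real_)
  )
}

#' SNR/CNR across the b-values of a series
#'
#' One row per b-value with the signal-ROI mean and SD and the SNR/CNR
#' against the background ROI, mirroring a b-value comparison table.
#'
#' @param series A `dwmr_series` from [generate_series()] (or any list
#'   with `images` and `bvalues`).
#' @param rois List with `signal` and `background` [roi_spec()]s, e.g.
#'   from [default_rois()].
#' @return Tibble of class `dwmr_bscan` with columns `bvalue`,
#'   `signal_mean`, `signal_sd`, `background_mean`, `background_sd`,
#'   `snr`, `cnr`.
#' @export
bvalue_scan <- function(series, rois) {
  stopifnot(length(series$images) == length(series$bvalues),
            length(series$images) >= 1)
  out <- purrr::map2_dfr(series$images, series$bvalues, function(img, b) {
    dplyr::bind_cols(tibble::tibble(bvalue = b), .roi_metrics(img, rois))
  })
  if (anyNA(out$snr)) {
    stop("SNR undefined at b = ",
         paste(out$bvalue[is.na(out$snr)], collapse = ", "),
         ": background ROI standard deviation is zero", call. = FALSE)
  }
  class(out) <- c("dwmr_bscan", class(out))
  out
}

# the sweep key column: b-value for scans, smoothing factor for sweeps
.key_col <- function(table) {
  for (k in c("bvalue", "d")) if (k %in% names(table)) return(k)
  stop("table has neither a 'bvalue' nor a 'd' column", call. = FALSE)
}

#' Working b-value: the row with maximal CNR
#'
#' Ties are broken toward the smaller b-value, preferring the shorter,
#' less attenuated acquisition.
#'
#' @param table A metrics table with a `cnr` column and a `bvalue` (or
#'   `d`) key column, e.g. from [bvalue_scan()].
#' @return The key (b-value) of the maximal-CNR row.
#' @export
select_working_bvalue <- function(table) {
  if (!nrow(table)) stop("empty metrics table", call. = FALSE)
  key <- table[[.key_col(table)]]
  min(key[table$cnr == max(table$cnr)])
}

#' Sweep the non-local means smoothing factor
#'
#' Denoises `img` at every d on the configured grid and measures SNR and
#' CNR with the same ROIs each time. Patch distances do not depend on d,
#' so the engine computes them once per search-window displacement and
#' reuses them across the whole grid.
#'
#' @param img Numeric matrix (typically the working-b image).
#' @param rois List with `signal` and `background` [roi_spec()]s.
#' @param cfg A [sweep_config()].
#' @param method `"nlm-fast"` (default; integral-image aggregation) or
#'   `"nlm"` (direct per-offset aggregation). The two are numerically
#'   equivalent.
#' @param params An [nlm_params()]; its `d` is ignored in favour of the
#'   grid.
#' @return Tibble of class `dwmr_sweep`, one row per d, columns `d`,
#'   `signal_mean`, `signal_sd`, `background_mean`, `background_sd`,
#'   `snr`, `cnr`; the unfiltered input's metrics are kept in
#'   `attr(, "input_metrics")`.
#' @export
sweep_smoothing_factor <- function(img, rois, cfg = sweep_config(),
                                   method = c("nlm-fast", "nlm"),
                                   params = nlm_params()) {
  method <- match.arg(method)
  stopifnot(inherits(cfg, "sweep_config"))
  d_grid <- seq(cfg$d_min, cfg$d_max, by = cfg$d_step)
  agg <- if (method == "nlm" || params$a > 0) "offset" else "integral"
  denoised <- .nlm_engine(img, params, d_grid, aggregation = agg,
                          symmetric = (method == "nlm-fast"))
  out <- purrr::map2_dfr(denoised, d_grid, function(den, d) {
    dplyr::bind_cols(tibble::tibble(d = d), .roi_metrics(den, rois))
  })
  attr(out, "input_metrics") <- .roi_metrics(img, rois)
  class(out) <- c("dwmr_sweep", class(out))
  out
}

#' Select the optimal smoothing factor from a sweep table
#'
#' Under the default `"plateau_knee"` policy, the optimum is the smallest
#' d whose CNR reaches `plateau_fraction` of the sweep's maximum CNR —
#' the first d on the plateau, balancing noise reduction against the
#' resolution loss that grows with d. Under `"max_cnr"` it is the
#' argmax-CNR d (ties toward smaller d).
#'
#' @param table A sweep table with `d` and `cnr` columns.
#' @param cfg A [sweep_config()] supplying the policy and plateau
#'   fraction.
#' @return The selected smoothing factor.
#' @export
select_optimal_d <- function(table, cfg = sweep_config()) {
  if (!nrow(table)) stop("empty sweep table", call. = FALSE)
  stopifnot(inherits(cfg, "sweep_config"))
  key <- table[[.key_col(table)]]
  if (cfg$optimum_policy == "max_cnr") {
    return(min(key[table$cnr == max(table$cnr)]))
  }
  thr <- cfg$plateau_fraction * max(table$cnr)
  min(key[table$cnr >= thr])
}

#' Truncated fold-change ratio
#'
#' Ratio of two positive quantities truncated (floored, never rounded)
#' to two decimals — the reporting convention for denoising improvement
#' factors. Truncation applies only at reporting; keep full precision
#' internally.
#'
#' @param numerator,denominator Positive scalars (vectorised).
#' @return `floor(100 * numerator / denominator) / 100`.
#' @examples
#' fold_change(215.81, 96.87)  # 2.22
#' fold_change(131.98, 43.63)  # 3.02
#' @export
fold_change <- function(numerator, denominator) {
  if (any(!(denominator > 0))) {
    stop("fold_change denominator must be > 0", call. = FALSE)
  }
  # the 1e-9 guard keeps ratios that are exact two-decimal values from
  # being truncated down by floating-point representation error
  floor(100 * numerator / denominator + 1e-9) / 100
}

#' Compare optimized NLM against the conventional filters
#'
#' Applies the median, adaptive Wiener, TV, and non-local means (at the
#' supplied smoothing factor) filters to the same image, measures SNR and
#' CNR for each with the same ROIs, and reports truncated fold-change
#' ratios of each method against the unfiltered image and of NLM against
#' each baseline. Optionally samples a line profile across an insert
#' boundary for every method for the resolution-preservation analysis.
#'
#' @param img Numeric matrix (the working-b image).
#' @param rois List with `signal` and `background` [roi_spec()]s.
#' @param nlm_d Smoothing factor for the NLM entry (e.g. from
#'   [select_optimal_d()]).
#' @param params An [nlm_params()] for everything but `d`.
#' @param settings A [filter_settings()] for the baselines.
#' @param profile Optional list with `start` and `end` (row, col) pairs;
#'   when given, [line_profile()] is sampled on every filtered image.
#' @return Object of class `dwmr_comparison`: list with `metrics` (tibble
#'   of method, signal/background stats, snr, cnr, snr_fold, cnr_fold vs
#'   the unfiltered image), `nlm_vs_baselines` (tibble of truncated NLM /
#'   baseline ratios), `profiles` (tibble or NULL), `nlm_d`, and
#'   `degenerate` (TRUE when the unfiltered image had no measurable
#'   noise, making folds meaningless).
#' @export
run_comparison_study <- function(img, rois, nlm_d,
                                 params = nlm_params(),
                                 settings = filter_settings(),
                                 profile = NULL) {
  stopifnot(inherits(params, "nlm_params"),
            inherits(settings, "filter_settings"), nlm_d > 0)
  nlm_par <- params; nlm_par$d <- nlm_d
  filtered <- list(
    none = img,
    median = median_filter(img, settings),
    wiener = wiener_filter(img, settings),
    tv = tv_denoise(img, settings),
    nlm = nlm_denoise_fast(img, nlm_par)
  )
  metrics <- purrr::imap_dfr(filtered, function(im, nm) {
    dplyr::bind_cols(tibble::tibble(method = nm), .roi_metrics(im, rois))
  })
  degenerate <- anyNA(metrics$snr) || anyNA(metrics$cnr)
  base <- metrics[metrics$method == "none", ]
  safe_fold <- function(a, b) {
    b <- rep_len(b, length(a))
    out <- rep(NA_real_, length(a))
    ok <- !is.na(a) & !is.na(b) & b > 0
    out[ok] <- fold_change(a[ok], b[ok])
    out
  }
  metrics$snr_fold <- safe_fold(metrics$snr, base$snr)
  metrics$cnr_fold <- safe_fold(metrics$cnr, base$cnr)
  nlm_row <- metrics[metrics$method == "nlm", ]
  base_rows <- metrics[metrics$method %in% c("median", "wiener", "tv"), ]
  nlm_vs <- tibble::tibble(
    baseline = base_rows$method,
    snr_fold = safe_fold(nlm_row$snr, base_rows$snr),
    cnr_fold = safe_fold(nlm_row$cnr, base_rows$cnr)
  )
  profiles <- NULL
  if (!is.null(profile)) {
    profiles <- purrr::imap_dfr(filtered, function(im, nm) {
      dplyr::bind_cols(tibble::tibble(method = nm),
                       line_profile(im, profile$start, profile$end))
    })
  }
  structure(list(metrics = metrics, nlm_vs_baselines = nlm_vs,
                 profiles = profiles, nlm_d = nlm_d,
                 degenerate = degenerate),
            class = "dwmr_comparison")
}

#' @export
print.dwmr_comparison <- function(x, ...) {
  cat(sprintf("<dwmr_comparison> NLM d = %g%s\n", x$nlm_d,
              if (x$degenerate) " (degenerate: no measurable noise)" else ""))
  print(x$metrics)
  invisible(x)
}
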