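#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a smoothing-factor sweep
#'
#' @param x A `dwmr_sweep` from [sweep_smoothing_factor()].
#' @param ... Unused.
#' @return Long tibble with columns `d`, `metric` (snr/cnr), `value`.
#' @exportS3Method generics::tidy
tidy.dwmr_sweep <- function(x, ...) {
  tibble::as_tibble(x)[, c("d", "snr", "cnr")] |>
    tidyr::pivot_longer(c("snr", "cnr"), names_to = "metric",
                        values_to = "value")
}

#' One-row summary of a smoothing-factor sweep
#'
#' @param x A `dwmr_sweep`.
#' @param cfg A [sweep_config()] used for the optimum rule.
#' @param ... Unused.
#' @return Tibble with the grid size, input SNR/CNR, selected d, and the
#'   metrics at the selected d.
#' @exportS3Method generics::glance
glance.dwmr_sweep <- function(x, cfg = sweep_config(), ...) {
  d_opt <- select_optimal_d(x, cfg)
  sel <- x[x$d == d_opt, ]
  inp <- attr(x, "input_metrics")
  tibble::tibble(
    n_d = nrow(x), d_opt = d_opt,
    snr_input = if (!is.null(inp)) inp$snr else NA_real_,
    cnr_input = if (!is.null(inp)) inp$cnr else NA_real_,
    snr_opt = sel$snr, cnr_opt = sel$cnr,
    snr_max = max(x$snr), cnr_max = max(x$cnr)
  )
}

#' @exportS3Method generics::tidy
tidy.dwmr_bscan <- function(x, ...) {
  tibble::as_tibble(x)[, c("bvalue", "snr", "cnr")] |>
    tidyr::pivot_longer(c("snr", "cnr"), names_to = "metric",
                        values_to = "value")
}

#' Tidy a comparison study
#'
#' @param x A `dwmr_comparison` from [run_comparison_study()].
#' @param ... Unused.
#' @return Long tibble with `method`, `metric`, `value`, `fold` (vs the
#'   unfiltered image).
#' @exportS3Method generics::tidy
tidy.dwmr_comparison <- function(x, ...) {
  m <- x$metrics
  dplyr::bind_rows(
    tibble::tibble(method = m$method, metric = "snr", value = m$snr,
                   fold = m$snr_fold),
    tibble::tibble(method = m$method, metric = "cnr", value = m$cnr,
                   fold = m$cnr_fold)
  )
}

#' @exportS3Method generics::glance
glance.dwmr_comparison <- function(x, ...) {
  nlm <- x$metrics[x$metrics$method == "nlm", ]
  tibble::tibble(
    nlm_d = x$nlm_d, degenerate = x$degenerate,
    snr_nlm = nlm$snr, cnr_nlm = nlm$cnr,
    snr_fold_nlm = nlm$snr_fold, cnr_fold_nlm = nlm$cnr_fold,
    best_baseline_snr = {
      b <- x$metrics[x$metrics$method %in% c("median", "wiener", "tv"), ]
      b$method[which.max(b$snr)]
    }
  )
}

#' Plot SNR/CNR against the smoothing factor
#'
#' @param object A `dwmr_sweep`.
#' @param cfg Optional [sweep_config()]; when given, the selected optimum
#'   is marked with a vertical line.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dwmr_sweep <- function(object, cfg = NULL, ...) {
  p <- ggplot2::ggplot(tidy.dwmr_sweep(object),
                       ggplot2::aes(.data$d, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = ggplot2::labeller(
                          metric = c(snr = "SNR", cnr = "CNR"))) +
    ggplot2::labs(x = "smoothing factor d", y = NULL,
                  title = "Denoising quality vs smoothing factor") +
    ggplot2::theme_minimal()
  if (!is.null(cfg)) {
    p <- p + ggplot2::geom_vline(xintercept = select_optimal_d(object, cfg),
                                 linetype = "dashed")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.dwmr_bscan <- function(object, ...) {
  ggplot2::ggplot(tidy.dwmr_bscan(object),
                  ggplot2::aes(.data$bvalue, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = ggplot2::labeller(
                          metric = c(snr = "SNR", cnr = "CNR"))) +
    ggplot2::labs(x = expression(b ~ (s/mm^2)), y = NULL,
                  title = "ROI quality across diffusion weightings") +
    ggplot2::theme_minimal()
}

#' Plot a comparison study
#'
#' Bar chart of SNR and CNR per method; when the study carries line
#' profiles, they are drawn in a second panel row.
#'
#' @param object A `dwmr_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dwmr_comparison <- function(object, ...) {
  td <- tidy.dwmr_comparison(object)
  td$method <- factor(td$method,
                      levels = c("none", "median", "wiener", "tv", "nlm"))
  ggplot2::ggplot(td, ggplot2::aes(.data$method, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = ggplot2::labeller(
                          metric = c(snr = "SNR", cnr = "CNR"))) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Denoiser comparison (ROI metrics)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.dwmr_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$position, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along segment (px)", y = "intensity",
                  title = "Signal intensity profile") +
    ggplot2::theme_minimal()
}

#' Raster plot of an image matrix
#'
#' @param img Numeric matrix.
#' @param title Optional plot title.
#' @return A ggplot with `geom_raster`, rows increasing downwards as in
#'   image space.
#' @export
plot_image <- function(img, title = NULL) {
  df <- tibble::tibble(
    row = as.vector(row(img)), col = as.vector(col(img)),
    value = as.vector(img)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "I", title = title) +
    ggplot2::theme_minimal()
}
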