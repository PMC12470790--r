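#' Define a rectangular region of interest
#'
#' Coordinates are 1-based and inclusive: the ROI covers rows
#' `origin[1] .. origin[1] + size[1] - 1` and likewise for columns.
#'
#' @param origin Length-2 (row, col) of the top-left pixel.
#' @param size Length-2 (height, width) in pixels; default the standard
#'   25 x 25 window.
#' @param role `"signal"` or `"background"`; informational.
#' @return An object of class `dwmr_roi`.
#' @export
roi_spec <- function(origin, size = c(25L, 25L),
                     role = c("signal", "background")) {
  role <- match.arg(role)
  stopifnot(length(origin) == 2, length(size) == 2, all(size >= 1),
            all(origin >= 1))
  structure(list(origin = as.integer(origin), size = as.integer(size),
                 role = role),
            class = "dwmr_roi")
}

#' Mean and standard deviation over an ROI
#'
#' Uses the population standard deviation (divisor n): with 625-pixel
#' ROIs the n / n-1 distinction is negligible but the convention is fixed
#' so results are exactly reproducible.
#'
#' @param img Numeric matrix.
#' @param roi A [roi_spec()], fully inside the image.
#' @return One-row tibble with columns `mean`, `sd`, `n`, `role`.
#' @export
roi_stats <- function(img, roi) {
  stopifnot(inherits(roi, "dwmr_roi"))
  r2 <- roi$origin + roi$size - 1L
  if (r2[1] > nrow(img) || r2[2] > ncol(img)) {
    stop("ROI extends outside the image", call. = FALSE)
  }
  px <- img[roi$origin[1]:r2[1], roi$origin[2]:r2[2]]
  n <- length(px)
  m <- mean(px)
  tibble::tibble(mean = m, sd = sqrt(sum((px - m)^2) / n), n = n,
                 role = roi$role)
}

# accept either a roi_stats() tibble/list or a bare (mean, sd) pair
.as_stats <- function(x) {
  if (is.numeric(x) && length(x) == 2) return(list(mean = x[1], sd = x[2]))
  list(mean = x$mean, sd = x$sd)
}

#' Signal-to-noise ratio from ROI statistics
#'
#' SNR = (signal ROI mean) / (background ROI standard deviation). The
#' background SD comes from a dedicated background region, not from the
#' signal ROI.
#'
#' @param signal,background ROI statistics as returned by [roi_stats()]
#'   (or a bare numeric `c(mean, sd)` pair).
#' @return Scalar SNR.
#' @export
compute_snr <- function(signal, background) {
  s <- .as_stats(signal); b <- .as_stats(background)
  if (!(b$sd > 0)) {
    stop("SNR undefined: background ROI standard deviation is zero",
         call. = FALSE)
  }
  s$mean / b$sd
}

#' Contrast-to-noise ratio from ROI statistics
#'
#' CNR = (signal mean - background mean) /
#' sqrt(signal sd^2 + background sd^2).
#'
#' @inheritParams compute_snr
#' @return Scalar CNR (antisymmetric under swapping the two ROIs).
#' @export
compute_cnr <- function(signal, background) {
  s <- .as_stats(signal); b <- .as_stats(background)
  denom <- sqrt(s$sd^2 + b$sd^2)
  if (!(denom > 0)) {
    stop("CNR undefined: both ROI standard deviations are zero",
         call. = FALSE)
  }
  (s$mean - b$mean) / denom
}

#' Estimate the apparent diffusion coefficient from a decay curve
#'
#' Under mono-exponential decay \eqn{S(b) = S(0)\exp(-b \cdot ADC)},
#' pairwise inversion against b = 0 gives
#' \eqn{ADC_b = \ln(S(0)/S(b)) / b} for every b > 0; the log-linear
#' method returns the negated slope of the least-squares fit of
#' \eqn{\ln S} on b. The two agree exactly when the decay is exactly
#' mono-exponential.
#'
#' @param signals Positive signal intensities (e.g. ROI means), one per
#'   b-value.
#' @param bvalues b-values in s/mm^2; the first must be 0.
#' @param method `"pairwise_to_b0"` (default) or `"loglinear"`.
#' @return For `"pairwise_to_b0"`, a tibble with columns `bvalue` and
#'   `adc` (mm^2/s), one row per b > 0; for `"loglinear"`, a single
#'   numeric ADC.
#' @examples
#' estimate_adc(c(925.93, 332.54), c(0, 1000))  # ~1024e-6 mm^2/s
#' @export
estimate_adc <- function(signals, bvalues,
                         method = c("pairwise_to_b0", "loglinear")) {
  method <- match.arg(method)
  stopifnot(length(signals) == length(bvalues), length(signals) >= 2)
  if (bvalues[1] != 0) stop("bvalues must start at 0", call. = FALSE)
  if (any(signals <= 0)) {
    stop("all signals must be positive for log-domain ADC estimation",
         call. = FALSE)
  }
  if (method == "pairwise_to_b0") {
    b <- bvalues[-1]
    tibble::tibble(bvalue = b, adc = log(signals[1] / signals[-1]) / b)
  } else {
    -unname(stats::coef(stats::lm(log(signals) ~ bvalues))[2])
  }
}

#' Sample an intensity profile along a line segment
#'
#' Bilinear samples at unit spacing from `start` to `end` (both length-2
#' (row, col), 1-based, inside the image). The endpoint is always
#' included, so positions run 0, 1, ..., up to the segment length.
#'
#' @param img Numeric matrix.
#' @param start,end Segment endpoints, (row, col).
#' @return Tibble of class `dwmr_profile` with columns `position` (pixel
#'   offset along the segment), `row`, `col`, `value`.
#' @export
line_profile <- function(img, start, end) {
  stopifnot(length(start) == 2, length(end) == 2)
  inb <- function(p) p[1] >= 1 && p[1] <= nrow(img) &&
    p[2] >= 1 && p[2] <= ncol(img)
  if (!inb(start) || !inb(end)) {
    stop("profile endpoints must lie inside the image", call. = FALSE)
  }
  len <- sqrt(sum((end - start)^2))
  pos <- if (len == 0) 0 else unique(c(seq(0, len, by = 1), len))
  t <- if (len == 0) 0 else pos / len
  rr <- start[1] + t * (end[1] - start[1])
  cc <- start[2] + t * (end[2] - start[2])
  r0 <- pmin(floor(rr), nrow(img) - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(cc), ncol(img) - 1L); c0 <- pmax(c0, 1L)
  fr <- rr - r0; fc <- cc - c0
  v <- (1 - fr) * (1 - fc) * img[cbind(r0, c0)] +
    (1 - fr) * fc * img[cbind(r0, c0 + 1L)] +
    fr * (1 - fc) * img[cbind(r0 + 1L, c0)] +
    fr * fc * img[cbind(r0 + 1L, c0 + 1L)]
  out <- tibble::tibble(position = pos, row = rr, col = cc, value = v)
  class(out) <- c("dwmr_profile", class(out))
  out
}

#' 10-90% edge width of an intensity profile
#'
#' Quantifies boundary sharpness: the distance over which the profile
#' rises from 10% to 90% of the plateau-to-plateau amplitude, linearly
#' interpolated between samples. Smaller is sharper; smoothing widens the
#' edge. The transition must be detectable: the difference between the
#' medians of the leading and trailing plateau segments has to exceed 5%
#' of the profile's dynamic range.
#'
#' @param profile A [line_profile()] tibble (or anything with `position`
#'   and `value` columns).
#' @param plateau_fraction Fraction of the profile length treated as
#'   plateau at each end when testing for a detectable transition.
#' @return Edge width in pixels (scalar).
#' @export
edge_width <- function(profile, plateau_fraction = 0.25) {
  pos <- profile$position; val <- profile$value
  stopifnot(length(pos) == length(val), length(pos) >= 3)
  k <- max(1L, floor(length(val) * plateau_fraction))
  lead_med <- stats::median(utils::head(val, k))
  trail_med <- stats::median(utils::tail(val, k))
  rng <- max(val) - min(val)
  if (!(rng > 0) || abs(trail_med - lead_med) < 0.05 * rng) {
    stop("no detectable edge transition in the profile", call. = FALSE)
  }
  rising <- trail_med > lead_med
  v <- if (rising) val else rev(val)
  p <- if (rising) pos else max(pos) - rev(pos)
  lo <- min(val); hi <- max(val)
  cross <- function(level) {
    idx <- which(v[-1] >= level & v[-length(v)] < level |
                   v[-1] > level & v[-length(v)] <= level)
    if (!length(idx)) return(NA_real_)
    i <- idx[1]
    p[i] + (level - v[i]) / (v[i + 1] - v[i]) * (p[i + 1] - p[i])
  }
  x10 <- cross(lo + 0.1 * (hi - lo))
  x90 <- cross(lo + 0.9 * (hi - lo))
  if (is.na(x10) || is.na(x90)) {
    stop("no detectable edge transition in the profile", call. = FALSE)
  }
  abs(x90 - x10)
}
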