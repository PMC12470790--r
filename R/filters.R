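#' Settings for the conventional comparator filters
#'
#' @param kernel Odd window edge length in pixels for the median and
#'   adaptive Wiener filters (default 5, i.e. 5 x 5).
#' @param tv_lambda Total-variation regularization weight multiplying the
#'   TV term of the ROF objective (default 0.2).
#' @param tv_iters Iteration budget of the TV dual solver (default 200).
#' @param tv_tol Relative-change stopping tolerance of the TV solver.
#' @return An object of class `filter_settings`.
#' @export
filter_settings <- function(kernel = 5L, tv_lambda = 0.2, tv_iters = 200L,
                            tv_tol = 1e-5) {
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L) {
    stop("kernel must be odd and >= 3", call. = FALSE)
  }
  if (!(tv_lambda > 0)) stop("tv_lambda must be > 0", call. = FALSE)
  if (!(tv_iters >= 1)) stop("tv_iters must be >= 1", call. = FALSE)
  structure(list(kernel = kernel, tv_lambda = tv_lambda,
                 tv_iters = as.integer(tv_iters), tv_tol = tv_tol),
            class = "filter_settings")
}

# stack the kernel^2 shifted copies of the reflect-padded image as columns
.window_stack <- function(img, kernel) {
  r <- (kernel - 1L) %/% 2L
  P <- .pad_image(img, r, "reflect")
  nr <- nrow(img); nc <- ncol(img)
  offs <- seq(-r, r)
  cols <- vector("list", kernel^2)
  i <- 1L
  for (ox in offs) {
    for (oy in offs) {
      cols[[i]] <- as.vector(P[r + seq_len(nr) + oy, r + seq_len(nc) + ox])
      i <- i + 1L
    }
  }
  do.call(cbind, cols)
}

#' Median filter
#'
#' Each pixel is replaced by the median of its `kernel` x `kernel`
#' neighborhood, reflect-padded at the borders.
#'
#' @param img Numeric matrix.
#' @param settings A [filter_settings()]; only `kernel` is used.
#' @return Filtered matrix of the same shape.
#' @export
median_filter <- function(img, settings = filter_settings()) {
  stopifnot(inherits(settings, "filter_settings"))
  k <- settings$kernel
  W <- .window_stack(img, k)
  n <- nrow(W)
  # sort each row in one vectorised order() call, then read the middle
  sorted <- matrix(t(W)[order(rep(seq_len(n), each = k^2), t(W))],
                   nrow = n, byrow = TRUE)
  mid <- (k^2 + 1L) %/% 2L
  matrix(sorted[, mid], nrow(img), ncol(img))
}

#' Locally adaptive (Lee) Wiener filter
#'
#' Classic minimum-mean-square-error shrinkage toward the local mean:
#' `out = mu + gain * (img - mu)` with
#' `gain = max(0, var_loc - noise_var) / var_loc` clamped to \[0, 1\],
#' where `mu` and `var_loc` are the mean and variance over the
#' `kernel` x `kernel` window (reflect-padded). With `noise_var = "auto"`
#' the noise variance is estimated as the mean of all local variances,
#' the convention of common image-processing toolboxes.
#'
#' @param img Numeric matrix.
#' @param settings A [filter_settings()]; only `kernel` is used.
#' @param noise_var Noise variance, or `"auto"` (default).
#' @return Filtered matrix of the same shape.
#' @export
wiener_filter <- function(img, settings = filter_settings(),
                          noise_var = "auto") {
  stopifnot(inherits(settings, "filter_settings"))
  k <- settings$kernel
  r <- (k - 1L) %/% 2L
  P <- .pad_image(img, r, "reflect")
  rows0 <- r + seq_len(nrow(img)); cols0 <- r + seq_len(ncol(img))
  mu <- .box_sum_at(P, r, rows0, cols0) / k^2
  m2 <- .box_sum_at(P^2, r, rows0, cols0) / k^2
  v <- pmax(m2 - mu^2, 0)
  if (identical(noise_var, "auto")) {
    nv <- mean(v)
  } else {
    if (!(is.numeric(noise_var) && length(noise_var) == 1 && noise_var >= 0)) {
      stop("noise_var must be \"auto\" or a single number >= 0",
           call. = FALSE)
    }
    nv <- noise_var
  }
  gain <- ifelse(v > 0, pmin(pmax((v - nv) / v, 0), 1), 0)
  mu + gain * (img - mu)
}

# forward-difference gradient with Neumann boundary (last row/col zero)
.tv_grad <- function(u) {
  gx <- cbind(u[, -1, drop = FALSE] - u[, -ncol(u), drop = FALSE], 0)
  gy <- rbind(u[-1, , drop = FALSE] - u[-nrow(u), , drop = FALSE], 0)
  list(gy = gy, gx = gx)
}

# divergence, the negative adjoint of .tv_grad (p[0] = 0 convention;
# the dual field keeps its last row/col at zero so the Neumann boundary
# is implicit)
.tv_div <- function(py, px) {
  dy <- py - rbind(0, py[-nrow(py), , drop = FALSE])
  dx <- px - cbind(0, px[, -ncol(px), drop = FALSE])
  dy + dx
}

# isotropic ROF energy 0.5||u - f||^2 + lambda * TV(u)
.tv_energy <- function(u, f, lambda) {
  g <- .tv_grad(u)
  0.5 * sum((u - f)^2) + lambda * sum(sqrt(g$gy^2 + g$gx^2))
}

#' Total-variation (ROF) denoising
#'
#' Approximately minimizes the Rudin-Osher-Fatemi objective
#' \eqn{\tfrac12\|u - f\|_2^2 + \lambda\,TV(u)} with isotropic total
#' variation, using the dual projection iteration (Chambolle's scheme,
#' step 0.248). Iterations stop at `tv_iters` or when the relative change
#' of the iterate falls below `tv_tol`.
#'
#' @param img Numeric matrix.
#' @param settings A [filter_settings()]; uses `tv_lambda`, `tv_iters`,
#'   `tv_tol`.
#' @return Filtered matrix with attributes `converged` (logical; `FALSE`
#'   with a warning when the budget is exhausted before the tolerance is
#'   met) and `energy` (the ROF energy after each iteration).
#' @export
tv_denoise <- function(img, settings = filter_settings()) {
  stopifnot(inherits(settings, "filter_settings"))
  lambda <- settings$tv_lambda
  f <- img
  nr <- nrow(f); nc <- ncol(f)
  py <- matrix(0, nr, nc); px <- matrix(0, nr, nc)
  tau <- 0.248
  u <- f
  energy <- numeric(0)
  converged <- FALSE
  for (it in seq_len(settings$tv_iters)) {
    u_prev <- u
    g <- .tv_grad(.tv_div(py, px) - f / lambda)
    denom <- 1 + tau * sqrt(g$gy^2 + g$gx^2)
    py <- (py + tau * g$gy) / denom
    px <- (px + tau * g$gx) / denom
    u <- f - lambda * .tv_div(py, px)
    energy <- c(energy, .tv_energy(u, f, lambda))
    rel <- sqrt(sum((u - u_prev)^2)) / max(sqrt(sum(u_prev^2)), 1e-300)
    if (rel < settings$tv_tol) { converged <- TRUE; break }
  }
  if (!converged && settings$tv_iters > 1) {
    warning("TV solver reached its iteration budget before tolerance; ",
            "returning the last iterate", call. = FALSE)
  }
  attr(u, "converged") <- converged
  attr(u, "energy") <- energy
  u
}
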