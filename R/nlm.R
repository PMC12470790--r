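#' Non-local means parameters
#'
#' @param d Smoothing factor (> 0) on unit-normalized intensities. The
#'   filter weight between two pixels is `exp(-dist / d^2)` where `dist`
#'   is the (Gaussian-weighted mean) squared patch difference, so on
#'   images normalized to \[0, 1\] useful values of `d` are roughly
#'   0.001-0.15: of the order of the noise standard deviation.
#' @param patch_radius Patch half-width in pixels; default 2 gives the
#'   standard 5 x 5 similarity patch.
#' @param search_radius Search-window half-width; default 7 gives the
#'   standard 15 x 15 window.
#' @param a Standard deviation (pixels) of the Gaussian kernel weighting
#'   patch offsets in the distance; `a = 0` (default) means uniform patch
#'   weights, to which the Gaussian form reduces as `a` grows large.
#' @param self_weight_policy How the center pixel weights itself:
#'   `"max_of_others"` (default; the maximum weight given to any other
#'   pixel in the window, standard practice to avoid self-dominance) or
#'   `"one"` (weight exactly 1 before normalization).
#' @param border_policy Padding at image borders: `"reflect"` (default,
#'   mirror with edge duplication) or `"replicate"` (edge extension).
#' @return An object of class `nlm_params`.
#' @export
nlm_params <- function(d = 0.013, patch_radius = 2L, search_radius = 7L,
                       a = 0,
                       self_weight_policy = c("max_of_others", "one"),
                       border_policy = c("reflect", "replicate")) {
  self_weight_policy <- match.arg(self_weight_policy)
  border_policy <- match.arg(border_policy)
  if (!(d > 0)) stop("smoothing factor d must be > 0", call. = FALSE)
  if (!(patch_radius >= 1)) stop("patch_radius must be >= 1", call. = FALSE)
  if (!(search_radius >= patch_radius)) {
    stop("search_radius must be >= patch_radius", call. = FALSE)
  }
  if (!(a >= 0)) stop("a must be >= 0", call. = FALSE)
  structure(
    list(d = d, patch_radius = as.integer(patch_radius),
         search_radius = as.integer(search_radius), a = a,
         self_weight_policy = self_weight_policy,
         border_policy = border_policy),
    class = "nlm_params"
  )
}

#' Max-normalize image intensities to \[0, 1\]
#'
#' The smoothing factor `d` is defined on unit-scale intensities, so
#' filtering first divides by the image maximum and restores it
#' afterwards. Exposed because metrics and sweeps sometimes want the same
#' normalization.
#'
#' @param img Numeric matrix with at least one positive pixel.
#' @return List with `image` (matrix in \[0, 1\]) and `scale` (the former
#'   maximum); `image * scale` reproduces the input.
#' @export
normalize_intensity <- function(img) {
  m <- max(img)
  if (!(is.finite(m) && m > 0)) {
    stop("cannot normalize an image with no positive pixel", call. = FALSE)
  }
  list(image = img / m, scale = m)
}

# mirror (edge-duplicating) or edge-replicating index into 1..n
.pad_index <- function(idx, n, policy) {
  if (policy == "replicate") return(pmin(pmax(idx, 1L), n))
  # reflect about the half-sample boundary: ... 2 1 | 1 2 ... n | n n-1 ...
  period <- 2L * n
  idx <- ((idx - 1L) %% period + period) %% period  # 0 .. 2n-1
  ifelse(idx < n, idx + 1L, period - idx)
}

# pad a matrix by r pixels on every side under the given border policy
.pad_image <- function(img, r, policy) {
  ri <- .pad_index(seq(1L - r, nrow(img) + r), nrow(img), policy)
  ci <- .pad_index(seq(1L - r, ncol(img) + r), ncol(img), policy)
  img[ri, ci, drop = FALSE]
}

# patch offset kernel: (2p+1)^2 weights normalized to sum 1
.patch_kernel <- function(patch_radius, a) {
  off <- seq(-patch_radius, patch_radius)
  g <- if (a > 0) {
    outer(off, off, function(oy, ox) exp(-(oy^2 + ox^2) / (2 * a^2)))
  } else {
    matrix(1, length(off), length(off))
  }
  g / sum(g)
}

#' Gaussian-weighted squared distance between two patches
#'
#' The patch dissimilarity driving the non-local means weights: the
#' kernel-weighted mean of squared intensity differences over patch
#' offsets, with a Gaussian kernel of width `a` (uniform when `a = 0`).
#' Symmetric in its two pixel arguments and zero for identical patches.
#'
#' @param img Numeric matrix.
#' @param m,n Pixels as length-2 (row, col), 1-based.
#' @param params An [nlm_params()].
#' @return Nonnegative scalar.
#' @export
patch_distance <- function(img, m, n, params = nlm_params()) {
  p <- params$patch_radius
  pad <- .pad_image(img, p, params$border_policy)
  g <- .patch_kernel(p, params$a)
  k <- 2L * p + 1L
  pm <- pad[m[1] + seq_len(k) - 1L, m[2] + seq_len(k) - 1L]
  pn <- pad[n[1] + seq_len(k) - 1L, n[2] + seq_len(k) - 1L]
  sum(g * (pm - pn)^2)
}

# shifted copy of padded matrix: out[r,c] = P[r+dy, c+dx], 0 where invalid
.shift_plane <- function(P, dy, dx) {
  nr <- nrow(P); nc <- ncol(P)
  out <- matrix(0, nr, nc)
  r_src <- max(1L, 1L + dy):min(nr, nr + dy)
  c_src <- max(1L, 1L + dx):min(nc, nc + dx)
  out[r_src - dy, c_src - dx] <- P[r_src, c_src]
  out
}

# running sums down the rows / across the columns, in place; a plain
# loop of whole-row (whole-column) adds beats apply() here because it
# avoids one closure call per line
.cumsum_rows <- function(X) {
  for (i in seq_len(nrow(X))[-1]) X[i, ] <- X[i, ] + X[i - 1L, ]
  X
}
.cumsum_cols <- function(X) {
  for (j in seq_len(ncol(X))[-1]) X[, j] <- X[, j] + X[, j - 1L]
  X
}

# integral-image box sum of X over (2p+1)^2 windows, evaluated on the
# interior grid rows0/cols0 (padded coordinates of the original pixels)
.box_sum_at <- function(X, p, rows0, cols0) {
  I <- .cumsum_cols(.cumsum_rows(X))
  Iz <- matrix(0, nrow(X) + 1L, ncol(X) + 1L)
  Iz[-1, -1] <- I
  r2 <- rows0 + p; r1 <- rows0 - p - 1L
  c2 <- cols0 + p; c1 <- cols0 - p - 1L
  Iz[r2 + 1L, c2 + 1L, drop = FALSE] -
    Iz[r1 + 1L, c2 + 1L, drop = FALSE] -
    Iz[r2 + 1L, c1 + 1L, drop = FALSE] +
    Iz[r1 + 1L, c1 + 1L, drop = FALSE]
}

# Workhorse shared by nlm_denoise(), nlm_denoise_fast() and the smoothing
# sweep: loops over search-window displacements once, computes the patch
# distance plane for every pixel, and accumulates the weighted average for
# every requested d. `aggregation` chooses how patch sums are formed:
#  - "offset": explicit sum over patch offsets, O(patch area) per pixel per
#    displacement (the direct transcription of the weighted distance);
#  - "integral": running (cumulative) sums so each box sum costs O(1) per
#    pixel; only valid for the uniform patch kernel (a = 0).
# With `symmetric = TRUE` only half the displacements are visited: the
# distance plane for -(dy, dx) is the +(dy, dx) plane translated by the
# displacement, so it is read off an extended evaluation grid instead of
# being recomputed. Purely an evaluation-order change; the accumulated
# sums are identical.
.nlm_engine <- function(img, params, d_values, aggregation,
                        symmetric = FALSE) {
  s <- params$search_radius; p <- params$patch_radius
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 2L * s + 1L || nc < 2L * s + 1L) {
    stop(sprintf("image (%d x %d) is smaller than the %d x %d search window",
                 nr, nc, 2 * s + 1, 2 * s + 1), call. = FALSE)
  }
  norm <- normalize_intensity(img)
  R <- s + p
  P <- .pad_image(norm$image, R, params$border_policy)
  rows0 <- R + seq_len(nr); cols0 <- R + seq_len(nc)
  # evaluation grid for distance planes: the original pixels, extended by
  # the search radius when the symmetry shortcut needs translated reads
  rows_e <- if (symmetric) (R - s) + seq_len(nr + 2L * s) else rows0
  cols_e <- if (symmetric) (R - s) + seq_len(nc + 2L * s) else cols0
  g <- .patch_kernel(p, params$a)
  offs <- seq(-p, p)
  nd <- length(d_values)
  d2 <- d_values^2
  num <- vector("list", nd); den <- vector("list", nd)
  wmax <- vector("list", nd)
  for (k in seq_len(nd)) {
    num[[k]] <- matrix(0, nr, nc); den[[k]] <- matrix(0, nr, nc)
    wmax[[k]] <- matrix(0, nr, nc)
  }
  accumulate <- function(dist, vals) {
    for (k in seq_len(nd)) {
      w <- exp(-dist / d2[k])
      num[[k]] <<- num[[k]] + w * vals
      den[[k]] <<- den[[k]] + w
      wmax[[k]] <<- pmax(wmax[[k]], w)
    }
  }
  disp <- expand.grid(dy = seq(-s, s), dx = seq(-s, s))
  disp <- disp[disp$dy != 0 | disp$dx != 0, ]
  if (symmetric) disp <- disp[disp$dy > 0 | (disp$dy == 0 & disp$dx > 0), ]
  for (i in seq_len(nrow(disp))) {
    dy <- disp$dy[i]; dx <- disp$dx[i]
    Sh <- .shift_plane(P, dy, dx)
    D <- (P - Sh)^2
    dist <- if (aggregation == "integral") {
      .box_sum_at(D, p, rows_e, cols_e) / (2 * p + 1)^2
    } else {
      acc <- matrix(0, length(rows_e), length(cols_e))
      for (iy in seq_along(offs)) {
        for (ix in seq_along(offs)) {
          acc <- acc + g[iy, ix] *
            D[rows_e + offs[iy], cols_e + offs[ix], drop = FALSE]
        }
      }
      acc
    }
    if (!symmetric) {
      accumulate(dist, Sh[rows0, cols0, drop = FALSE])
    } else {
      ctr_r <- s + seq_len(nr); ctr_c <- s + seq_len(nc)
      accumulate(dist[ctr_r, ctr_c, drop = FALSE],
                 P[rows0 + dy, cols0 + dx, drop = FALSE])
      accumulate(dist[ctr_r - dy, ctr_c - dx, drop = FALSE],
                 P[rows0 - dy, cols0 - dx, drop = FALSE])
    }
  }
  out <- vector("list", nd)
  for (k in seq_len(nd)) {
    ws <- if (params$self_weight_policy == "one") {
      matrix(1, nr, nc)
    } else {
      # max of the other weights; floored at the smallest normal double so
      # a pixel whose every neighbour weight underflows to 0 returns its
      # own value instead of 0/0
      pmax(wmax[[k]], .Machine$double.xmin)
    }
    out[[k]] <- (num[[k]] + ws * norm$image) / (den[[k]] + ws) * norm$scale
  }
  out
}

#' Non-local means denoising (direct form)
#'
#' Replaces every pixel by a convex combination of the pixels in its
#' search window, weighted by patch similarity:
#' \eqn{NL[f](m) = \sum_n \omega_{m,n} f(n)} with
#' \eqn{\omega_{m,n} \propto \exp(-\|v(m)-v(n)\|^2_{2,a} / d^2)} and the
#' normalizer \eqn{Z(m)} making the weights sum to one. The image is
#' max-normalized internally so `d` always refers to unit-scale
#' intensities; the output is restored to the input scale and always lies
#' within the input range.
#'
#' @param img Numeric nonnegative matrix, at least as large as the search
#'   window.
#' @param params An [nlm_params()].
#' @return Denoised matrix of the same shape.
#' @seealso [nlm_denoise_fast()] for the numerically equivalent
#'   accelerated form, [nlm_weight_field()] to inspect weights at a pixel.
#' @export
nlm_denoise <- function(img, params = nlm_params()) {
  stopifnot(inherits(params, "nlm_params"))
  .nlm_engine(img, params, params$d, aggregation = "offset")[[1]]
}

#' Non-local means denoising (integral-image accelerated)
#'
#' Numerically equivalent to [nlm_denoise()] (maximum absolute difference
#' below 1e-8 on the unit intensity scale) but organised per search-window
#' displacement: for each displacement one squared-difference plane is
#' formed and patch sums are read from its running (integral) sums in
#' O(1) per pixel, instead of O(patch area). With the Gaussian patch
#' kernel (`a > 0`) box sums do not apply and the per-offset accumulation
#' is used, still vectorised over the whole plane per displacement.
#'
#' @inheritParams nlm_denoise
#' @return Denoised matrix of the same shape.
#' @export
nlm_denoise_fast <- function(img, params = nlm_params()) {
  stopifnot(inherits(params, "nlm_params"))
  agg <- if (params$a > 0) "offset" else "integral"
  .nlm_engine(img, params, params$d, aggregation = agg,
              symmetric = TRUE)[[1]]
}

#' Non-local means weights at one pixel
#'
#' Assembles the normalized weight field \eqn{\omega_{m,n}} a single
#' target pixel receives over its search window, mainly for inspection
#' and for verifying the normalization contract (weights sum to 1).
#'
#' @param img Numeric matrix.
#' @param pixel Length-2 (row, col), 1-based.
#' @param params An [nlm_params()].
#' @return Tibble with columns `row`, `col`, `dy`, `dx`, `distance`,
#'   `weight`; weights sum to 1.
#' @export
nlm_weight_field <- function(img, pixel, params = nlm_params()) {
  stopifnot(inherits(params, "nlm_params"))
  s <- params$search_radius; p <- params$patch_radius
  norm <- normalize_intensity(img)
  R <- s + p
  P <- .pad_image(norm$image, R, params$border_policy)
  g <- .patch_kernel(p, params$a)
  k <- 2L * p + 1L
  m_pad <- pixel + R
  grid <- expand.grid(dy = seq(-s, s), dx = seq(-s, s))
  patch_at <- function(r, c) {
    P[r - p + seq_len(k) - 1L, c - p + seq_len(k) - 1L]
  }
  pm <- patch_at(m_pad[1], m_pad[2])
  dist <- mapply(function(dy, dx) {
    sum(g * (pm - patch_at(m_pad[1] + dy, m_pad[2] + dx))^2)
  }, grid$dy, grid$dx)
  w <- exp(-dist / params$d^2)
  self <- grid$dy == 0 & grid$dx == 0
  w[self] <- if (params$self_weight_policy == "one") 1 else
    max(w[!self], .Machine$double.xmin)
  tibble::tibble(
    row = pixel[1] + grid$dy, col = pixel[2] + grid$dx,
    dy = grid$dy, dx = grid$dx, distance = dist, weight = w / sum(w)
  )
}
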