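# Independent brute-force oracles. These deliberately re-derive everything
# from the definitions with plain loops and share no code with the package
# internals.

# mirror index with edge duplication: ... 2 1 | 1 2 ... n | n n-1 ...
oracle_mirror <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_pixel <- function(img, r, c, border = "reflect") {
  n <- nrow(img); m <- ncol(img)
  if (border == "replicate") {
    img[min(max(r, 1), n), min(max(c, 1), m)]
  } else {
    img[oracle_mirror(r, n), oracle_mirror(c, m)]
  }
}

# patch dissimilarity: kernel-weighted mean of squared differences
oracle_patch_dist <- function(img, m, n, p, a = 0, border = "reflect") {
  tot <- 0; wtot <- 0
  for (oy in -p:p) {
    for (ox in -p:p) {
      g <- if (a > 0) exp(-(oy^2 + ox^2) / (2 * a^2)) else 1
      fm <- oracle_pixel(img, m[1] + oy, m[2] + ox, border)
      fn <- oracle_pixel(img, n[1] + oy, n[2] + ox, border)
      tot <- tot + g * (fm - fn)^2
      wtot <- wtot + g
    }
  }
  tot / wtot
}

# literal transcription of the non-local means definition: loop over every
# pixel and every displacement in its search window, weight by
# exp(-patch distance / d^2), self weight by policy, normalize.
oracle_nlm <- function(img, d, p = 2L, s = 7L, a = 0,
                       self_weight = "max_of_others", border = "reflect") {
  scale <- max(img)
  f <- img / scale
  nr <- nrow(f); nc <- ncol(f)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      wsum <- 0; vsum <- 0; wmax <- 0
      for (dy in -s:s) {
        for (dx in -s:s) {
          if (dy == 0 && dx == 0) next
          dist <- oracle_patch_dist(f, c(i, j), c(i + dy, j + dx), p, a,
                                    border)
          w <- exp(-dist / d^2)
          wmax <- max(wmax, w)
          wsum <- wsum + w
          vsum <- vsum + w * oracle_pixel(f, i + dy, j + dx, border)
        }
      }
      ws <- if (self_weight == "one") 1 else max(wmax, .Machine$double.xmin)
      out[i, j] <- (vsum + ws * f[i, j]) / (wsum + ws)
    }
  }
  out * scale
}

# per-pixel sort-based median filter
oracle_median <- function(img, k) {
  r <- (k - 1) %/% 2
  out <- img
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      vals <- numeric(0)
      for (oy in -r:r) for (ox in -r:r) {
        vals <- c(vals, oracle_pixel(img, i + oy, j + ox))
      }
      out[i, j] <- sort(vals)[(k^2 + 1) %/% 2]
    }
  }
  out
}

# windowed-moments adaptive Wiener filter
oracle_wiener <- function(img, k, noise_var) {
  r <- (k - 1) %/% 2
  out <- img
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      vals <- numeric(0)
      for (oy in -r:r) for (ox in -r:r) {
        vals <- c(vals, oracle_pixel(img, i + oy, j + ox))
      }
      mu <- mean(vals)
      v <- mean((vals - mu)^2)
      gain <- if (v > 0) min(max((v - noise_var) / v, 0), 1) else 0
      out[i, j] <- mu + gain * (img[i, j] - mu)
    }
  }
  out
}

# two-pass loop mean / population SD
oracle_roi_stats <- function(img, r1, c1, h, w) {
  vals <- numeric(0)
  for (i in r1:(r1 + h - 1)) for (j in c1:(c1 + w - 1)) {
    vals <- c(vals, img[i, j])
  }
  m <- sum(vals) / length(vals)
  s2 <- sum((vals - m)^2) / length(vals)
  list(mean = m, sd = sqrt(s2))
}

# fixture: reproducible positive test image
random_image <- function(nr, nc, seed = 1, lo = 0.1, hi = 1) {
  set.seed(seed)
  matrix(stats::runif(nr * nc, lo, hi), nr, nc)
}
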