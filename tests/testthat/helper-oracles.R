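# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementation paths they check.

# L1-ball containment erosion: pixel kept iff every in-bounds offset with
# |dr| + |dc| <= radius is foreground and no part of the ball leaves the mask
# (out-of-bounds counts as background).
brute_erode_diamond <- function(mask, radius) {
  n <- nrow(mask); p <- ncol(mask)
  out <- matrix(FALSE, n, p)
  for (r in seq_len(n)) for (cc in seq_len(p)) {
    keep <- TRUE
    for (dr in -radius:radius) {
      for (dc in -(radius - abs(dr)):(radius - abs(dr))) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1 || rr > n || c2 < 1 || c2 > p || mask[rr, c2] == 0) {
          keep <- FALSE; break
        }
      }
      if (!keep) break
    }
    out[r, cc] <- keep && mask[r, cc] != 0
  }
  out
}

# Direct 2-D Gaussian convolution with half-sample symmetric reflection.
brute_gaussian_blur <- function(img, sigma) {
  K <- ceiling(4 * sigma)
  g <- dnorm(-K:K, sd = sigma); g <- g / sum(g)
  refl <- function(x, n) {
    while (any(x < 1 | x > n)) {
      x <- ifelse(x < 1, 1 - x, x)
      x <- ifelse(x > n, 2 * n + 1 - x, x)
    }
    x
  }
  n <- nrow(img); p <- ncol(img)
  out <- matrix(0, n, p)
  for (r in seq_len(n)) for (cc in seq_len(p)) {
    acc <- 0
    for (i in -K:K) for (j in -K:K) {
      acc <- acc + g[i + K + 1] * g[j + K + 1] *
        img[refl(r + i, n), refl(cc + j, p)]
    }
    out[r, cc] <- acc
  }
  out
}

# Solid square label mask centered in a larger field.
square_label <- function(side, field = side + 20L, label = 1L) {
  m <- matrix(0L, field, field)
  o <- floor((field - side) / 2)
  m[(o + 1):(o + side), (o + 1):(o + side)] <- label
  m
}

# Welch statistic from first principles.
brute_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
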