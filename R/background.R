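#' Background estimation and subtraction
#'
#' Two background models are used. Widefield fields are corrected by
#' pseudo-flat-field subtraction: a heavily Gaussian-blurred copy of the
#' image (sigma 50 px by default) is subtracted from the original, removing
#' smooth illumination structure while leaving cell-scale detail. Confocal
#' vacuole images are corrected by rolling-ball subtraction: a grayscale
#' ball of fixed radius is rolled under the intensity surface and the
#' resulting envelope subtracted.
#'
#' @name background
NULL

.blur_cache <- new.env(parent = emptyenv())

reflect_index <- function(x, n) {
  # half-sample symmetric reflection: ... 3 2 1 | 1 2 3 ... n | n n-1 ...
  while (any(x < 1L | x > n)) {
    x <- ifelse(x < 1L, 1L - x, x)
    x <- ifelse(x > n, 2L * n + 1L - x, x)
  }
  x
}

blur_operator <- function(n, sigma) {
  key <- paste0("n", n, "_s", sigma)
  if (!is.null(.blur_cache[[key]])) return(.blur_cache[[key]])
  K <- ceiling(4 * sigma)
  g <- stats::dnorm(-K:K, sd = sigma)
  g <- g / sum(g)
  A <- matrix(0, n, n)
  i <- seq_len(n)
  for (k in -K:K) {
    j <- reflect_index(i + k, n)
    idx <- cbind(i, j)
    A[idx] <- A[idx] + g[k + K + 1L]
  }
  .blur_cache[[key]] <- A
  A
}

#' Gaussian blur with reflective boundaries
#'
#' Separable Gaussian convolution, kernel truncated at 4 sigma, with
#' half-sample symmetric reflection at the image border (which avoids the
#' dark-edge artifacts that zero padding would introduce at the field
#' border). Implemented exactly as a pair of banded row/column operator
#' matrices, so each axis is a single matrix product.
#'
#' @param img numeric matrix
#' @param sigma standard deviation in px
#' @return blurred matrix of the same dimensions
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma > 0)
  R <- blur_operator(nrow(img), sigma)
  C <- blur_operator(ncol(img), sigma)
  R %*% img %*% t(C)
}

#' Pseudo-flat-field background subtraction
#'
#' Subtracts a sigma-`cfg$flatfield_sigma` Gaussian blur of the image from
#' the image itself. The result is signed and deliberately not clipped:
#' clipping would bias dim cells upward.
#'
#' @param img numeric matrix (single channel)
#' @param cfg a [run_config()]
#' @return signed numeric matrix
#' @export
flatfield_subtract <- function(img, cfg = run_config()) {
  img - gaussian_blur(img, cfg$flatfield_sigma)
}

ball_profile <- function(radius) {
  r <- floor(radius)
  d <- -r:r
  dx <- outer(d, rep(1, length(d)))
  dy <- outer(rep(1, length(d)), d)
  h2 <- radius^2 - dx^2 - dy^2
  h <- sqrt(pmax(h2, 0))
  h[h2 < 0] <- NA_real_  # outside the ball support
  list(offsets = d, height = h)
}

shift_pad <- function(m, dr, dc, fill) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  rs <- max(1L, 1L - dr):min(n, n - dr)
  cs <- max(1L, 1L - dc):min(p, p - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

ball_transform <- function(img, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  b <- ball_profile(radius)
  d <- b$offsets
  acc <- matrix(if (op == "erode") Inf else -Inf, nrow(img), ncol(img))
  for (i in seq_along(d)) for (j in seq_along(d)) {
    h <- b$height[i, j]
    if (is.na(h)) next
    if (op == "erode") {
      acc <- pmin(acc, shift_pad(img, d[i], d[j], Inf) - h)
    } else {
      acc <- pmax(acc, shift_pad(img, -d[i], -d[j], -Inf) + h)
    }
  }
  acc
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' ball structuring element of radius `cfg$rollingball_radius` (the envelope
#' traced by rolling the ball under the intensity surface) and subtracts it.
#' A flat image maps to zero; peaks narrower than the ball are preserved
#' while structure broader than the ball is removed. Tiny negative residues
#' from numeric error are clipped to zero.
#'
#' Cost grows with the ball area; intended for confocal frames and test
#' images, not for repeated batch use on large widefield fields (the
#' widefield branch of the pipeline uses [flatfield_subtract()]).
#'
#' @param img numeric matrix (single channel)
#' @param cfg a [run_config()]
#' @return background-subtracted matrix
#' @export
rolling_ball_subtract <- function(img, cfg = run_config()) {
  stopifnot(is.matrix(img), cfg$rollingball_radius > 0)
  bg <- ball_transform(ball_transform(img, cfg$rollingball_radius, "erode"),
                       cfg$rollingball_radius, "dilate")
  out <- img - bg
  out[out < 0 & out > -1e-8] <- 0
  out
}
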