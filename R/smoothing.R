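#' Gaussian smoothing of an 8-bit RGB image
#'
#' Per-channel 2-D Gaussian convolution, implemented separably. The kernel
#' is truncated at 4 standard deviations (radius `floor(4 * sigma)` pixels)
#' and renormalized; boundaries use edge-duplicating reflection
#' (`d c b a | a b c d ...`). The convolution runs in floating point and
#' the result is re-quantized to 8-bit once, half-away-from-zero.
#' `sigma = 0` (or any sigma small enough that the truncated kernel
#' collapses to a single tap) returns the input unchanged.
#'
#' @param image an [rgb_image()].
#' @param sigma Gaussian standard deviation in pixels (default 1).
#' @return The smoothed [rgb_image()].
#' @export
gaussian_smooth <- function(image, sigma = 1) {
  stopifnot(is_rgb_image(image), sigma >= 0)
  r <- floor(4 * sigma)
  if (sigma == 0 || r < 1) return(image)
  t0 <- (-r):r
  k <- exp(-t0^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(image)
  out <- array(0, dim = d)
  ri <- reflect_index(seq_len(d[1] + 2L * r) - r, d[1])
  ci <- reflect_index(seq_len(d[2] + 2L * r) - r, d[2])
  for (ch in 1:3) {
    m <- matrix(as.double(image[, , ch]), d[1], d[2])
    # row pass (vertical), then column pass (horizontal)
    pad <- m[ri, , drop = FALSE]
    v <- matrix(0, d[1], d[2])
    for (o in seq_along(k)) v <- v + k[o] * pad[(o - 1L) + seq_len(d[1]), , drop = FALSE]
    pad <- v[, ci, drop = FALSE]
    h <- matrix(0, d[1], d[2])
    for (o in seq_along(k)) h <- h + k[o] * pad[, (o - 1L) + seq_len(d[2]), drop = FALSE]
    out[, , ch] <- h
  }
  rgb_image(array(quantize8(out), dim = d))
}

# Map 1-based indices (possibly out of range) into 1..n by edge-duplicating
# reflection: ..., 2, 1 | 1, 2, ..., n | n, n-1, ...
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  j <- ((i - 1L) %% p + p) %% p
  ifelse(j < n, j + 1L, p - j)
}
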