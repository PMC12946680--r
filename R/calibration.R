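#' Patch-wise mean RGB values of reference regions
#'
#' For each polygon, collects the pixels whose centers fall inside it (see
#' [point_in_polygon()]) and returns the arithmetic per-channel mean. These
#' patch means are the input to the least-squares correction fit: the
#' calibration regresses on `n_patches` mean rows, not on every pixel.
#'
#' @param image an [rgb_image()].
#' @param patch_polygons list of polygons (two-column (x, y) matrices) in
#'   0-based pixel coordinates.
#' @return Numeric matrix `n_patches x 3` with columns `r, g, b`, values in
#'   0-255, one row per polygon.
#' @export
extract_patch_means <- function(image, patch_polygons) {
  stopifnot(is_rgb_image(image))
  if (!length(patch_polygons)) stop("no patch polygons supplied", call. = FALSE)
  d <- dim(image)
  out <- t(vapply(seq_along(patch_polygons), function(i) {
    px <- polygon_pixels(patch_polygons[[i]], d[2], d[1])
    if (nrow(px) == 0L)
      stop("patch polygon ", i, " encloses no pixel centers", call. = FALSE)
    idx <- px[, "y"] + 1L + px[, "x"] * d[1]
    c(mean(image[idx]),
      mean(image[idx + d[1] * d[2]]),
      mean(image[idx + 2L * d[1] * d[2]]))
  }, numeric(3)))
  colnames(out) <- c("r", "g", "b")
  out
}

#' Fit the 3x3 linear color-correction matrix
#'
#' Finds the 3x3 matrix `M` minimizing the Frobenius norm of
#' `measured %*% t(M) - target`, i.e. the ordinary least-squares map (no
#' intercept) from measured patch means to their known target values. With
#' exactly three independent patches the fit interpolates; with more it
#' averages noise down. Fit diagnostics (per-patch residual RMS and the
#' condition number of the measured matrix) are attached.
#'
#' @param measured,target numeric `n x 3` matrices of patch means (same
#'   patch order); `n >= 3` and `measured` must have rank 3.
#' @return A `correction_matrix` object: list with elements `M` (3x3),
#'   `residual_rms` (length `n`), `condition_number`, `n_patches`.
#' @export
fit_correction <- function(measured, target) {
  measured <- as.matrix(measured); target <- as.matrix(target)
  if (!identical(dim(measured), dim(target)))
    stop("measured and target must have identical dimensions", call. = FALSE)
  if (ncol(measured) != 3L || nrow(measured) < 3L)
    stop("need an n x 3 matrix with n >= 3 patches", call. = FALSE)
  kap <- condition_number(measured)
  if (!is.finite(kap) || kap > 1e8)
    stop("degenerate chart: measured patch matrix is rank-deficient or ",
         "ill-conditioned (condition number ", format(kap), ")", call. = FALSE)
  # normal equations solved via QR: measured %*% t(M) ~ target
  tM <- qr.solve(measured, target)
  M <- t(tM)
  dimnames(M) <- NULL
  resid <- measured %*% tM - target
  structure(
    list(M = M,
         residual_rms = sqrt(rowMeans(resid^2)),
         condition_number = kap,
         n_patches = nrow(measured)),
    class = "correction_matrix")
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat("<correction_matrix> 3x3 linear color correction\n")
  print(round(x$M, 5))
  cat(sprintf("patches: %d   condition number: %.3g   max residual RMS: %.4g\n",
              x$n_patches, x$condition_number, max(x$residual_rms)))
  invisible(x)
}

#' Apply a color correction to a whole image
#'
#' Every pixel `p` is mapped to `clip(round(M %*% p), 0, 255)` and stored
#' as 8-bit; rounding is half-away-from-zero, and quantization happens once
#' (the matrix is applied in floating point).
#'
#' @param image an [rgb_image()].
#' @param M a `correction_matrix` from [fit_correction()] or a bare 3x3
#'   numeric matrix.
#' @return The corrected [rgb_image()].
#' @export
apply_correction <- function(image, M) {
  stopifnot(is_rgb_image(image))
  if (inherits(M, "correction_matrix")) M <- M$M
  M <- as.matrix(M)
  stopifnot(identical(dim(M), c(3L, 3L)))
  d <- dim(image)
  out <- quantize8(img_to_mat(image) %*% t(M))
  mat_to_img(out, d[1], d[2])
}
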