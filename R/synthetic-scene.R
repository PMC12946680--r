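# Ground-truthed phantom scenes: a six-patch reference strip plus
# petal-shaped ROIs of known color composition, rendered under a known
# invertible 3x3 color distortion. Because the distortion is applied as
# measured = inv(M_true) %*% true, the correction matrix fitted from the
# rendered chart equals M_true itself, which makes recovery tests direct.

#' Specification of an in-image color reference strip
#'
#' Defines the chart patches (polygon + known target RGB). The default is a
#' horizontal strip of six 12x12 squares with targets spanning the full RGB
#' space (white, grey, red, green, blue, yellow); the 6x3 target matrix has
#' rank 3, which the constructor enforces, as a rank-deficient target set
#' cannot identify a 3x3 correction.
#'
#' @param patches list of `list(polygon =, target_rgb =)` entries; `NULL`
#'   for the default six-patch strip.
#' @param origin (x, y) of the default strip's top-left corner.
#' @param patch_size side length in pixels of the default square patches.
#' @param gap gap between default patches in pixels.
#' @return A `chart_spec` object.
#' @export
chart_spec <- function(patches = NULL, origin = c(4, 4), patch_size = 12,
                       gap = 4) {
  if (is.null(patches)) {
    targets <- rbind(c(255, 255, 255), c(128, 128, 128), c(200, 60, 50),
                     c(70, 160, 80), c(60, 90, 170), c(220, 200, 60))
    patches <- lapply(seq_len(nrow(targets)), function(i) {
      x0 <- origin[1] + (i - 1) * (patch_size + gap)
      list(polygon = rect_polygon(x0, origin[2], patch_size, patch_size),
           target_rgb = targets[i, ])
    })
  }
  if (length(patches) < 3L)
    stop("a chart needs at least 3 patches", call. = FALSE)
  tmat <- t(vapply(patches, function(p) as.numeric(p$target_rgb), numeric(3)))
  if (qr(tmat)$rank < 3L)
    stop("degenerate chart: target RGB matrix has rank < 3", call. = FALSE)
  areas <- vapply(patches, function(p) polygon_area(p$polygon), 0)
  if (any(areas < 25))
    stop("chart patches must each cover >= 25 px of area", call. = FALSE)
  structure(list(patches = patches, targets = tmat), class = "chart_spec")
}

#' Ground-truth color distortion model
#'
#' A known invertible 3x3 matrix `M_true` standing in for the combined
#' camera/illumination distortion that calibration corrects, plus i.i.d.
#' per-channel Gaussian pixel noise. Rendering applies `inv(M_true)` to
#' true colors, so the correction fitted downstream should recover
#' `M_true` directly.
#'
#' @param M_true invertible 3x3 matrix with condition number < 100.
#' @param noise_sd per-channel Gaussian SD in 0-255 units, `>= 0`.
#' @param seed integer seed for the noise stream.
#' @return A `distortion_model` object.
#' @export
distortion_model <- function(M_true = diag(3), noise_sd = 0, seed = 1L) {
  M_true <- as.matrix(M_true)
  stopifnot(identical(dim(M_true), c(3L, 3L)), noise_sd >= 0)
  kap <- condition_number(M_true)
  if (!is.finite(kap) || kap >= 100)
    stop("M_true must be invertible with condition number < 100 (got ",
         format(kap), ")", call. = FALSE)
  structure(list(M_true = M_true, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "distortion_model")
}

#' Render a ground-truthed chart + petal phantom image
#'
#' Paints the chart patches at their target colors and each petal ROI with
#' a known color composition on a dark background, then distorts every
#' pixel as `measured = clip(round(inv(M_true) %*% true + noise), 0, 255)`.
#' The true (undistorted) image and per-ROI color/count ground truth are
#' kept alongside so downstream stages can be checked exactly.
#'
#' Petal ROI pixels are assigned colors in contiguous blocks (row-major
#' raster order) whose sizes follow the requested weights, so the true
#' per-color pixel counts are known exactly.
#'
#' @param chart a [chart_spec()].
#' @param distortion a [distortion_model()].
#' @param petal_spec list with one entry per petal ROI:
#'   `list(polygon =, colors = m x 3 matrix, weights = m proportions)`
#'   (`weights` defaults to equal).
#' @param width,height image dimensions in pixels.
#' @param background_rgb dark background triplet (default `c(30, 30, 30)`,
#'   below the standard `V < 0.5` exclusion threshold).
#' @return A `scene_phantom`: list with `image` (measured), `true_image`,
#'   `chart`, `petal_rois`, `petal_truth` (per ROI
#'   `data.frame(r, g, b, count)` sorted by descending count),
#'   `background_rgb`, `distortion`, and `measured_means_exact` (the
#'   noise-free, unquantized measured patch means `targets %*% t(inv(M))`,
#'   on which the fitted correction recovers `M_true` to machine
#'   precision; means extracted from the rendered 8-bit image additionally
#'   carry per-channel quantization error of up to 0.5/255).
#' @export
simulate_scene <- function(chart = chart_spec(),
                           distortion = distortion_model(),
                           petal_spec = list(),
                           width = 160, height = 120,
                           background_rgb = c(30, 30, 30)) {
  stopifnot(inherits(chart, "chart_spec"), inherits(distortion, "distortion_model"))
  truth <- array(0L, dim = c(height, width, 3L))
  for (ch in 1:3) truth[, , ch] <- as.integer(background_rgb[ch])
  npix <- height * width

  paint <- function(arr, pix, rgbmat) {
    # pix: n x 2 (x, y); rgbmat: n x 3 (recycled if one row)
    if (nrow(rgbmat) == 1L) rgbmat <- rgbmat[rep(1L, nrow(pix)), , drop = FALSE]
    idx <- pix[, "y"] + 1L + pix[, "x"] * height
    arr[idx] <- as.integer(rgbmat[, 1])
    arr[idx + npix] <- as.integer(rgbmat[, 2])
    arr[idx + 2L * npix] <- as.integer(rgbmat[, 3])
    arr
  }

  all_pix <- list()
  for (i in seq_along(chart$patches)) {
    p <- chart$patches[[i]]
    pix <- polygon_pixels(p$polygon, width, height)
    if (nrow(pix) == 0L)
      stop("chart patch ", i, " falls outside the image", call. = FALSE)
    all_pix[[length(all_pix) + 1L]] <- pix
    truth <- paint(truth, pix, matrix(as.numeric(p$target_rgb), 1))
  }

  petal_rois <- lapply(petal_spec, `[[`, "polygon")
  petal_truth <- vector("list", length(petal_spec))
  for (i in seq_along(petal_spec)) {
    ps <- petal_spec[[i]]
    cols <- as.matrix(ps$colors)
    stopifnot(ncol(cols) == 3L)
    w <- ps$weights %||% rep(1, nrow(cols))
    stopifnot(length(w) == nrow(cols), all(w > 0))
    pix <- polygon_pixels(ps$polygon, width, height)
    if (nrow(pix) == 0L)
      stop("petal ROI ", i, " encloses no pixel centers", call. = FALSE)
    all_pix[[length(all_pix) + 1L]] <- pix
    # block partition by cumulative weight: counts sum exactly to the pixel total
    cuts <- floor(cumsum(w) / sum(w) * nrow(pix))
    counts <- diff(c(0L, cuts))
    assign_rgb <- cols[rep(seq_len(nrow(cols)), counts), , drop = FALSE]
    truth <- paint(truth, pix, assign_rgb)
    keep <- counts > 0
    petal_truth[[i]] <- data.frame(r = cols[keep, 1], g = cols[keep, 2],
                                   b = cols[keep, 3], count = counts[keep])
    petal_truth[[i]] <- petal_truth[[i]][order(-petal_truth[[i]]$count,
                                               petal_truth[[i]]$r * 65536 +
                                               petal_truth[[i]]$g * 256 +
                                               petal_truth[[i]]$b), , drop = FALSE]
    rownames(petal_truth[[i]]) <- NULL
  }

  # non-overlap check across all painted regions
  codes <- unlist(lapply(all_pix, function(p) p[, "y"] * width + p[, "x"]))
  if (anyDuplicated(codes))
    stop("chart patches / petal ROIs overlap", call. = FALSE)

  Minv <- solve(distortion$M_true)
  true_img <- rgb_image(truth)
  meas <- img_to_mat(true_img) %*% t(Minv)
  if (distortion$noise_sd > 0) {
    meas <- meas + with_local_seed(distortion$seed,
      matrix(rnorm(length(meas), 0, distortion$noise_sd), nrow = nrow(meas)))
  }
  measured <- mat_to_img(quantize8(meas), height, width)

  structure(list(image = measured,
                 true_image = true_img,
                 chart = chart,
                 petal_rois = petal_rois,
                 petal_truth = petal_truth,
                 background_rgb = as.numeric(background_rgb),
                 distortion = distortion,
                 # exact (pre-quantization, noise-free) measured patch means:
                 # the quantity the matrix-recovery identity holds on at
                 # machine precision; image-extracted means add ~0.5/255
                 # quantization noise per channel
                 measured_means_exact = chart$targets %*% t(Minv)),
            class = "scene_phantom")
}

#' @export
print.scene_phantom <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<scene_phantom> %d x %d px, %d chart patches, %d petal ROIs, noise_sd = %g\n",
              d[2], d[1], length(x$chart$patches), length(x$petal_rois),
              x$distortion$noise_sd))
  invisible(x)
}
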