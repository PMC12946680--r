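#' Palette extraction parameters
#'
#' Bundles the tunables of the dominant-color pipeline: smoothing strength,
#' brightness exclusion threshold, and palette depth per ROI. Defaults match
#' the pipeline's standard configuration: `sigma = 1` pixel of Gaussian
#' noise smoothing, exclusion of pixels with HSV value `V < 0.5` (shadow and
#' dark background), and the 20 most frequent colors per ROI.
#'
#' @param sigma Gaussian SD in pixels, `>= 0`.
#' @param v_min value-channel exclusion threshold in `[0, 1]`; pixels with
#'   `V = max(R, G, B) / 255 < v_min` are dropped.
#' @param k number of dominant colors retained per ROI, `>= 1`.
#' @return A `palette_params` list.
#' @export
palette_params <- function(sigma = 1, v_min = 0.5, k = 20) {
  stopifnot(sigma >= 0, v_min >= 0, v_min <= 1, k >= 1)
  structure(list(sigma = sigma, v_min = v_min, k = as.integer(k)),
            class = "palette_params")
}

#' Pixels of an image inside a polygonal ROI
#'
#' Returns the RGB values of all pixels whose centers fall inside the
#' polygon, under the same even-odd inclusion rule as
#' [extract_patch_means()].
#'
#' @param image an [rgb_image()].
#' @param roi polygon: two-column (x, y) matrix, >= 3 vertices, 0-based.
#' @return Integer `n x 3` matrix (columns `r, g, b`), one row per pixel,
#'   in row-major raster order.
#' @export
mask_roi <- function(image, roi) {
  stopifnot(is_rgb_image(image))
  d <- dim(image)
  px <- polygon_pixels(roi, d[2], d[1])
  if (nrow(px) == 0L)
    stop("ROI polygon encloses no pixel centers", call. = FALSE)
  idx <- px[, "y"] + 1L + px[, "x"] * d[1]
  out <- cbind(r = image[idx],
               g = image[idx + d[1] * d[2]],
               b = image[idx + 2L * d[1] * d[2]])
  out
}

#' Brightness filter on the HSV value channel
#'
#' Keeps a pixel iff `V >= v_min`, where `V = max(R, G, B) / 255`. Dark
#' background and shadow pixels are thereby excluded before frequency
#' counting; the exclusion is strict (`V < v_min` drops).
#'
#' @param pixels integer `n x 3` pixel matrix as from [mask_roi()].
#' @param v_min threshold in `[0, 1]` (default 0.5).
#' @return The retained rows of `pixels`.
#' @export
filter_value <- function(pixels, v_min = 0.5) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) return(pixels)
  v <- pmax(pixels[, 1], pmax(pixels[, 2], pixels[, 3])) / 255
  pixels[v >= v_min, , drop = FALSE]
}

#' Top-k most frequent 8-bit colors
#'
#' Exact frequency counting over full 8-bit RGB triplets (no binning). The
#' `k` most frequent colors are returned in descending count order; count
#' ties break by ascending lexicographic (R, G, B). If fewer than `k`
#' distinct colors exist, all are returned with a warning.
#'
#' @param pixels integer `n x 3` pixel matrix (after [filter_value()]).
#' @param k number of colors to keep.
#' @param roi_index optional index reported in the empty-ROI error.
#' @return `data.frame(r, g, b, count)` with at most `k` rows.
#' @export
top_k_colors <- function(pixels, k = 20, roi_index = NA_integer_) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L)
    stop("ROI ", roi_index, ": no pixels remain after filtering", call. = FALSE)
  stopifnot(k >= 1)
  code <- pixels[, 1] * 65536 + pixels[, 2] * 256 + pixels[, 3]
  u <- sort(unique(code))
  cnt <- tabulate(match(code, u), nbins = length(u))
  if (length(u) < k)
    warning("ROI ", roi_index, ": only ", length(u),
            " distinct colors (k = ", k, ")")
  ord <- order(-cnt, u)[seq_len(min(k, length(u)))]
  data.frame(r = u[ord] %/% 65536,
             g = (u[ord] %/% 256) %% 256,
             b = u[ord] %% 256,
             count = cnt[ord])
}

#' Compile per-ROI dominant colors into one palette
#'
#' Plain concatenation in ROI order, without deduplication: a color
#' dominant in two ROIs appears twice. With `n` ROIs each contributing
#' min(k, distinct) colors, the palette holds the sum of those counts
#' (e.g. 20 ROIs x 20 colors = 400 entries).
#'
#' @param per_roi_lists list of `data.frame(r, g, b, count)` as returned by
#'   [top_k_colors()], one per ROI.
#' @return A `petal_palette`: `data.frame(r, g, b, count, roi)`.
#' @export
compile_palette <- function(per_roi_lists) {
  if (!length(per_roi_lists) || !any(vapply(per_roi_lists, nrow, 0L) > 0))
    stop("all ROIs are empty; nothing to compile", call. = FALSE)
  out <- do.call(rbind, lapply(seq_along(per_roi_lists), function(i) {
    d <- per_roi_lists[[i]]
    if (nrow(d) == 0L) return(NULL)
    cbind(d, roi = i)
  }))
  rownames(out) <- NULL
  class(out) <- c("petal_palette", "data.frame")
  out
}

#' Sort a palette by hue
#'
#' Stable ascending sort on HSV hue (normalized to `[0, 1)`); hue ties
#' break by ascending (S, V, R, G, B). Achromatic colors (S = 0) carry
#' hue 0 and therefore sort before saturated reds.
#'
#' @param palette a `petal_palette` from [compile_palette()].
#' @return The palette rows reordered; a `hue` column is added.
#' @export
hue_sort <- function(palette) {
  if (nrow(palette) == 0L) return(palette)
  hsv <- t(grDevices::rgb2hsv(t(as.matrix(palette[, c("r", "g", "b")])),
                              maxColorValue = 255))
  palette$hue <- hsv[, 1]
  ord <- order(hsv[, 1], hsv[, 2], hsv[, 3],
               palette$r, palette$g, palette$b, method = "radix")
  out <- palette[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("petal_palette", "data.frame")
  out
}

#' Render a palette as a horizontal color bar
#'
#' One vertical stripe per palette entry, in palette order, left to right;
#' stripe boundaries at `floor(i * width / n)` so widths differ by at most
#' one pixel. Typically called on a hue-sorted palette so that the bar
#' reads as a perceptual hue sweep.
#'
#' @param palette a non-empty `petal_palette`.
#' @param width_px,height_px bar dimensions in pixels; `width_px` must be
#'   at least the number of entries.
#' @return An [rgb_image()] of the bar.
#' @export
render_bar <- function(palette, width_px = 400, height_px = 40) {
  n <- nrow(palette)
  if (n == 0L) stop("palette is empty", call. = FALSE)
  if (width_px < n)
    stop("bar width ", width_px, " px is narrower than the palette (",
         n, " entries)", call. = FALSE)
  bounds <- floor((0:n) * width_px / n)
  arr <- array(0L, dim = c(height_px, width_px, 3L))
  for (i in seq_len(n)) {
    cols <- (bounds[i] + 1L):bounds[i + 1L]
    arr[, cols, 1L] <- palette$r[i]
    arr[, cols, 2L] <- palette$g[i]
    arr[, cols, 3L] <- palette$b[i]
  }
  rgb_image(arr)
}

#' Dominant-color palette of a corrected image
#'
#' End-to-end convenience running the fixed pipeline order:
#' smooth (on the quantized 8-bit input) -> mask each ROI -> exclude
#' `V < v_min` pixels -> exact top-k frequency count per ROI -> compile ->
#' hue sort.
#'
#' @param image a color-corrected [rgb_image()].
#' @param rois list of ROI polygons.
#' @param params a [palette_params()].
#' @return A hue-sorted `petal_palette`.
#' @export
extract_palette <- function(image, rois, params = palette_params()) {
  stopifnot(is_rgb_image(image), length(rois) >= 1)
  sm <- gaussian_smooth(image, params$sigma)
  per_roi <- lapply(seq_along(rois), function(i) {
    px <- filter_value(mask_roi(sm, rois[[i]]), params$v_min)
    top_k_colors(px, params$k, roi_index = i)
  })
  hue_sort(compile_palette(per_roi))
}
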