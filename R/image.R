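#' 8-bit RGB raster images
#'
#' `rgb_image()` wraps an H x W x 3 integer array of 8-bit channel values
#' (0-255, row-major, origin top-left) in a light S3 class used throughout
#' the package. Pixel coordinates are 0-based with `x` = column and
#' `y` = row; the center of pixel `(x, y)` lies at `(x + 0.5, y + 0.5)`.
#'
#' @param data numeric array of dimension `c(height, width, 3)` with values
#'   in 0-255 (fractional values are rejected; quantize first).
#' @return An `rgb_image` object (integer array with class attribute).
#' @examples
#' img <- rgb_image(array(128L, dim = c(4, 6, 3)))
#' dim(img)
#' @export
rgb_image <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[3] != 3L)
    stop("`data` must be an H x W x 3 array", call. = FALSE)
  if (anyNA(data) || any(data < 0) || any(data > 255))
    stop("channel values must lie in [0, 255]", call. = FALSE)
  if (any(data != floor(data)))
    stop("channel values must be whole numbers; quantize first", call. = FALSE)
  storage.mode(data) <- "integer"
  structure(data, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels, 8-bit RGB\n", d[2], d[1]))
  invisible(x)
}

is_rgb_image <- function(x) inherits(x, "rgb_image")

# Flatten to an N x 3 double matrix (pixel rows in column-major raster
# order), and rebuild. Internal plumbing for per-pixel linear maps.
img_to_mat <- function(img) {
  d <- dim(img)
  matrix(as.double(img), ncol = 3L, dimnames = list(NULL, c("r", "g", "b")))
}

mat_to_img <- function(m, height, width) {
  rgb_image(array(as.integer(m), dim = c(height, width, 3L)))
}

#' Read an RGB image from PNG or TIFF
#'
#' Alpha channels are dropped with a warning; grayscale or paletted images
#' are rejected. Inputs with more than 8 bits per channel are re-quantized
#' to 8-bit with a warning.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return An [rgb_image()].
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop("cannot parse PNG '", path, "': ",
                                            conditionMessage(e), call. = FALSE)),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop("cannot parse TIFF '", path, "': ",
                                             conditionMessage(e), call. = FALSE)),
    stop("unsupported image format '", ext, "' (PNG or TIFF expected)",
         call. = FALSE)
  )
  if (length(dim(arr)) == 2L)
    stop("grayscale image '", path, "': 3-channel RGB required", call. = FALSE)
  nc <- dim(arr)[3]
  if (nc == 4L) {
    warning("dropping alpha channel of '", path, "'")
    arr <- arr[, , 1:3, drop = FALSE]
  } else if (nc != 3L) {
    stop("image '", path, "' has ", nc, " channels; 3-channel RGB required",
         call. = FALSE)
  }
  scaled <- arr * 255
  if (any(abs(scaled - round(scaled)) > 1e-9))
    warning("'", path, "' has more than 8 bits per channel; re-quantized to 8-bit")
  rgb_image(array(as.integer(round_half_away(scaled)), dim = dim(arr)))
}

#' Write an RGB image as PNG or TIFF
#'
#' @param image an [rgb_image()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(is_rgb_image(image))
  arr <- unclass(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, target = path),
    tif = ,
    tiff = tiff::writeTIFF(arr, where = path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}
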