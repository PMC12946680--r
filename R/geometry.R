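# Polygon rasterization. One inclusion rule is used everywhere (chart
# patches, petal ROIs, scene rendering): a pixel belongs to a polygon iff
# its CENTER (x + 0.5, y + 0.5) is inside under the even-odd rule; a center
# lying exactly on an edge counts as inside. Polygons are closed
# implicitly and vertices are in 0-based (x, y) pixel coordinates.

#' Even-odd point-in-polygon test
#'
#' Vectorized crossing-number test with the convention that points exactly
#' on a polygon edge are inside. Used both for patch/ROI rasterization and
#' as the shared inclusion rule of the whole pipeline.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly numeric matrix with two columns (x, y), one vertex per row,
#'   at least 3 rows; the polygon is closed implicitly.
#' @return Logical vector, `TRUE` where the point is inside or on an edge.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L)
    stop("polygon must be a matrix of >= 3 (x, y) vertices", call. = FALSE)
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- logical(length(px))
  onedge <- logical(length(px))
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    seg_len <- abs(x2 - x1) + abs(y2 - y1)
    if (seg_len > 0) {
      cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
      within <- px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
                py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
      onedge <- onedge | (abs(cross) <= eps * max(1, seg_len) & within)
      crosses <- (y1 > py) != (y2 > py)
      if (any(crosses)) {
        xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
        flip <- crosses & (px < xint)
        flip[is.na(flip)] <- FALSE
        inside <- xor(inside, flip)
      }
    }
    j <- i
  }
  inside | onedge
}

# 0-based (x, y) integer coordinates of the pixels of a `width` x `height`
# raster whose centers fall inside `poly`. Scans only the polygon's
# bounding box.
polygon_pixels <- function(poly, width, height) {
  poly <- as.matrix(poly)
  x0 <- max(0L, floor(min(poly[, 1])))
  x1 <- min(width - 1L, ceiling(max(poly[, 1])))
  y0 <- max(0L, floor(min(poly[, 2])))
  y1 <- min(height - 1L, ceiling(max(poly[, 2])))
  if (x1 < x0 || y1 < y0)
    return(cbind(x = integer(0), y = integer(0)))
  g <- expand.grid(x = x0:x1, y = y0:y1)
  keep <- point_in_polygon(g$x + 0.5, g$y + 0.5, poly)
  cbind(x = as.integer(g$x[keep]), y = as.integer(g$y[keep]))
}

# Shoelace area (always >= 0)
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Axis-aligned rectangle polygon helper: covers pixels x0..(x0+w-1),
# y0..(y0+h-1) exactly under the center rule.
rect_polygon <- function(x0, y0, w, h) {
  cbind(x = c(x0, x0 + w, x0 + w, x0),
        y = c(y0, y0, y0 + h, y0 + h))
}
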