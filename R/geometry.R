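# All coordinates are 0-based (row, col); boxes and tile windows are
# half-open [min, max). Masks store a cropped logical raster plus the global
# offset of its origin, so stitching is plain offset arithmetic.

#' Construct a pixel mask
#'
#' A mask is a cropped 2-D logical raster together with the (row, col)
#' offset of its origin in the global image frame (0-based), and an object
#' class label.
#'
#' @param pixels Logical matrix; at least one `TRUE` pixel.
#' @param offset Integer vector `c(row, col)`, both `>= 0`.
#' @param label Object class string.
#' @return An object of class `"eq_mask"`.
#' @export
new_mask <- function(pixels, offset = c(0L, 0L), label = "buchnera") {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    stop("mask pixels must be a logical matrix")
  }
  if (nrow(pixels) == 0L || ncol(pixels) == 0L) stop("mask raster is empty")
  if (!any(pixels)) stop("mask has no TRUE pixel")
  offset <- as.integer(round(offset))
  if (length(offset) != 2L || any(offset < 0L)) {
    stop("mask offset must be two non-negative integers (row, col)")
  }
  structure(list(pixels = pixels, offset = offset, label = as.character(label)),
            class = "eq_mask")
}

#' @export
print.eq_mask <- function(x, ...) {
  cat(sprintf("<mask '%s': %d px, raster %dx%d at offset (%d,%d)>\n",
              x$label, mask_area(x), nrow(x$pixels), ncol(x$pixels),
              x$offset[1], x$offset[2]))
  invisible(x)
}

#' Number of pixels in a mask
#' @param mask An `eq_mask`.
#' @return Integer pixel count.
#' @export
mask_area <- function(mask) sum(mask$pixels)

#' Trim a mask raster to its tight extent
#'
#' Drops all-`FALSE` border rows/columns and adjusts the offset so the
#' global pixel set is unchanged.
#'
#' @param mask An `eq_mask`.
#' @return The trimmed `eq_mask`.
#' @export
mask_trim <- function(mask) {
  rows <- which(rowSums(mask$pixels) > 0)
  cols <- which(colSums(mask$pixels) > 0)
  r0 <- rows[1]; r1 <- rows[length(rows)]
  c0 <- cols[1]; c1 <- cols[length(cols)]
  new_mask(mask$pixels[r0:r1, c0:c1, drop = FALSE],
           mask$offset + c(r0 - 1L, c0 - 1L), mask$label)
}

#' Construct a half-open bounding box
#'
#' @param row_min,col_min,row_max,col_max Integers; `[min, max)` on both
#'   axes, so `row_max > row_min` and `col_max > col_min`.
#' @return An object of class `"eq_bbox"`.
#' @export
new_bbox <- function(row_min, col_min, row_max, col_max) {
  b <- as.integer(round(c(row_min, col_min, row_max, col_max)))
  if (b[3] <= b[1] || b[4] <= b[2]) {
    stop("bbox max must be strictly greater than min on both axes")
  }
  structure(stats::setNames(b, c("row_min", "col_min", "row_max", "col_max")),
            class = "eq_bbox")
}

#' Tight bounding box of a mask, in global coordinates
#' @param mask An `eq_mask`.
#' @return An `eq_bbox` (half-open).
#' @export
mask_bbox <- function(mask) {
  rows <- which(rowSums(mask$pixels) > 0)
  cols <- which(colSums(mask$pixels) > 0)
  new_bbox(mask$offset[1] + rows[1] - 1L,
           mask$offset[2] + cols[1] - 1L,
           mask$offset[1] + rows[length(rows)],
           mask$offset[2] + cols[length(cols)])
}

#' Construct a detection
#'
#' A detection couples a mask with its tight bounding box and a prediction
#' score in `[0.01, 1]` (0.01 meaning no resemblance to the target class, 1
#' meaning high resemblance).
#'
#' @param mask An `eq_mask`.
#' @param score Numeric in `[0.01, 1]`.
#' @return An object of class `"eq_detection"`.
#' @export
new_detection <- function(mask, score) {
  score <- as.numeric(score)
  if (length(score) != 1L || is.na(score) || score < 0.01 || score > 1) {
    stop("detection score must lie in [0.01, 1]")
  }
  structure(list(mask = mask, bbox = mask_bbox(mask), score = score),
            class = "eq_detection")
}

bbox_intersects <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

# Intersection pixel count of two masks via their overlapping raster windows.
mask_intersection_area <- function(a, b) {
  ba <- mask_bbox(a); bb <- mask_bbox(b)
  r0 <- max(ba[1], bb[1]); r1 <- min(ba[3], bb[3])
  c0 <- max(ba[2], bb[2]); c1 <- min(ba[4], bb[4])
  if (r1 <= r0 || c1 <= c0) return(0L)
  sub <- function(m) {
    m$pixels[(r0 - m$offset[1] + 1L):(r1 - m$offset[1]),
             (c0 - m$offset[2] + 1L):(c1 - m$offset[2]), drop = FALSE]
  }
  sum(sub(a) & sub(b))
}

#' Intersection over union of two masks
#'
#' Computed on global-coordinate pixel sets: `|A n B| / |A u B|`.
#' Disjoint masks return 0; identical masks return 1.
#'
#' @param a,b `eq_mask` objects in the same global frame.
#' @return Numeric in `[0, 1]`.
#' @export
iou <- function(a, b) {
  inter <- mask_intersection_area(a, b)
  if (inter == 0L) return(0)
  inter / (mask_area(a) + mask_area(b) - inter)
}

#' Rasterize a polygon to a mask
#'
#' Fills the polygon under the pixel-center-inside rule (even-odd crossing
#' test): pixel `(r, c)` spans the unit square `[c, c+1) x [r, r+1)` in
#' continuous `(x, y)` coordinates and is set iff its center
#' `(c + 0.5, r + 0.5)` falls inside the polygon. Boundary pixels are
#' resolved by that rule alone.
#'
#' @param vertices Two-column numeric matrix of `(x, y)` points (x = column
#'   direction, y = row direction), at least 3 rows, all within the image.
#' @param image_shape Integer `c(rows, cols)` of the global frame.
#' @param label Class label for the resulting mask.
#' @return An `eq_mask` cropped to the polygon's pixel extent.
#' @export
polygon_to_mask <- function(vertices, image_shape, label = "buchnera") {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L) {
    stop("polygon needs at least 3 (x, y) vertices")
  }
  if (any(vertices[, 1] < 0) || any(vertices[, 2] < 0) ||
      any(vertices[, 1] > image_shape[2]) || any(vertices[, 2] > image_shape[1])) {
    stop("polygon vertices fall outside the image bounds")
  }
  if (abs(polygon_area(vertices)) < .Machine$double.eps) {
    stop("degenerate polygon with zero area")
  }
  c0 <- max(0L, floor(min(vertices[, 1])))
  c1 <- min(image_shape[2] - 1L, ceiling(max(vertices[, 1])))
  r0 <- max(0L, floor(min(vertices[, 2])))
  r1 <- min(image_shape[1] - 1L, ceiling(max(vertices[, 2])))
  cols <- c0:c1; rows <- r0:r1
  px <- rep(cols + 0.5, each = length(rows))
  py <- rep(rows + 0.5, times = length(cols))
  inside <- points_in_polygon(px, py, vertices)
  raster <- matrix(inside, nrow = length(rows), ncol = length(cols))
  if (!any(raster)) stop("polygon covers no pixel center")
  mask_trim(new_mask(raster, c(r0, c0), label))
}

# Even-odd crossing-number test, vectorized over query points.
points_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Shoelace area of a polygon
#' @param vertices Two-column `(x, y)` matrix.
#' @return Signed area (positive for counter-clockwise vertex order).
#' @export
polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Pixels covered by at least one mask
#'
#' @param masks List of `eq_mask` in one global frame (possibly empty).
#' @return Integer pixel count of the union.
#' @export
union_area <- function(masks) {
  if (length(masks) == 0L) return(0L)
  r0 <- min(vapply(masks, function(m) m$offset[1], integer(1)))
  c0 <- min(vapply(masks, function(m) m$offset[2], integer(1)))
  r1 <- max(vapply(masks, function(m) m$offset[1] + nrow(m$pixels), integer(1)))
  c1 <- max(vapply(masks, function(m) m$offset[2] + ncol(m$pixels), integer(1)))
  acc <- matrix(FALSE, nrow = r1 - r0, ncol = c1 - c0)
  for (m in masks) {
    rr <- (m$offset[1] - r0 + 1L):(m$offset[1] - r0 + nrow(m$pixels))
    cc <- (m$offset[2] - c0 + 1L):(m$offset[2] - c0 + ncol(m$pixels))
    acc[rr, cc] <- acc[rr, cc] | m$pixels
  }
  sum(acc)
}

# Full-frame logical raster of a mask (helper for transforms and rendering).
mask_to_frame <- function(mask, image_shape) {
  f <- matrix(FALSE, nrow = image_shape[1], ncol = image_shape[2])
  rr <- (mask$offset[1] + 1L):(mask$offset[1] + nrow(mask$pixels))
  cc <- (mask$offset[2] + 1L):(mask$offset[2] + ncol(mask$pixels))
  f[rr, cc] <- mask$pixels
  f
}

frame_to_mask <- function(frame, label = "buchnera") {
  if (!any(frame)) return(NULL)
  mask_trim(new_mask(frame, c(0L, 0L), label))
}

# Translate a mask by (drow, dcol); clips at the global origin and, when an
# image shape is given, at the far edge. Returns NULL when nothing is left.
mask_translate <- function(mask, drow, dcol, image_shape = NULL) {
  off <- mask$offset + c(as.integer(drow), as.integer(dcol))
  px <- mask$pixels
  if (off[1] < 0L) {
    cut <- -off[1]
    if (cut >= nrow(px)) return(NULL)
    px <- px[(cut + 1L):nrow(px), , drop = FALSE]; off[1] <- 0L
  }
  if (off[2] < 0L) {
    cut <- -off[2]
    if (cut >= ncol(px)) return(NULL)
    px <- px[, (cut + 1L):ncol(px), drop = FALSE]; off[2] <- 0L
  }
  if (!is.null(image_shape)) {
    over_r <- off[1] + nrow(px) - image_shape[1]
    if (over_r > 0L) {
      if (over_r >= nrow(px)) return(NULL)
      px <- px[1:(nrow(px) - over_r), , drop = FALSE]
    }
    over_c <- off[2] + ncol(px) - image_shape[2]
    if (over_c > 0L) {
      if (over_c >= ncol(px)) return(NULL)
      px <- px[, 1:(ncol(px) - over_c), drop = FALSE]
    }
  }
  if (!any(px)) return(NULL)
  mask_trim(new_mask(px, off, mask$label))
}

# Centroid (row, col) of a mask in global coordinates.
mask_centroid <- function(mask) {
  idx <- which(mask$pixels, arr.ind = TRUE)
  c(mean(idx[, 1]) - 1 + mask$offset[1], mean(idx[, 2]) - 1 + mask$offset[2])
}
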