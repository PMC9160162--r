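# Frontend tiling and backend stitching. Inference tiles are 512 px with an
# 85 px overlap (stride 427); the final window on each axis is clamped to
# end at the image edge, which on a 2048 px side yields exactly 5 windows
# per axis (25 tiles). Training tiles are a non-overlapping 512 px grid.

TILE_SIZE_DEFAULT <- 512L
TILE_OVERLAP_DEFAULT <- 85L

axis_windows <- function(side, tile_size, overlap) {
  stride <- tile_size - overlap
  starts <- seq.int(0L, max(0L, side - tile_size), by = stride)
  last <- side - tile_size
  if (starts[length(starts)] != last) starts <- c(starts, last)
  lapply(starts, function(s) c(s, s + tile_size))
}

#' Overlapping tile windows for inference
#'
#' Windows are half-open `[start, end)` ranges at stride
#' `tile_size - overlap`; the final window per axis is clamped to end at
#' the image edge (which enlarges the last overlap). Every pixel is covered
#' by at least one window. A 2048 x 2048 image yields 5 x 5 = 25 tiles.
#'
#' @param shape Integer `c(rows, cols)`, both `>= tile_size`.
#' @param tile_size Tile side in px (default 512).
#' @param overlap Overlap between adjacent windows in px (default 85).
#' @return An object of class `"eq_tile_spec"`: `tile_size`, `overlap`, and
#'   `windows`, a list of `list(row = c(start, end), col = c(start, end))`.
#' @export
tile_spec <- function(shape, tile_size = TILE_SIZE_DEFAULT,
                      overlap = TILE_OVERLAP_DEFAULT) {
  shape <- as.integer(shape)
  if (any(shape < tile_size)) {
    stop(sprintf("images must be at least %d px per side", tile_size))
  }
  rw <- axis_windows(shape[1], tile_size, overlap)
  cw <- axis_windows(shape[2], tile_size, overlap)
  windows <- list()
  for (r in rw) for (cl in cw) {
    windows[[length(windows) + 1L]] <- list(row = r, col = cl)
  }
  structure(list(tile_size = as.integer(tile_size),
                 overlap = as.integer(overlap),
                 shape = shape, windows = windows),
            class = "eq_tile_spec")
}

crop_window <- function(image, w) {
  tile <- image[(w$row[1] + 1L):w$row[2], (w$col[1] + 1L):w$col[2],
                drop = FALSE]
  attr(tile, "window") <- w
  tile
}

#' Crop an image into overlapping inference tiles
#'
#' @param img An `eq_annotated_image` or intensity matrix, `>= 512` px per
#'   side.
#' @param tile_size,overlap See [tile_spec()].
#' @return List with `spec` (`eq_tile_spec`) and `tiles` (list of tile
#'   matrices, each carrying its window as the `"window"` attribute).
#' @export
tile_inference <- function(img, tile_size = TILE_SIZE_DEFAULT,
                           overlap = TILE_OVERLAP_DEFAULT) {
  image <- if (inherits(img, "eq_annotated_image")) img$image else img
  spec <- tile_spec(dim(image), tile_size, overlap)
  tiles <- lapply(spec$windows, function(w) crop_window(image, w))
  list(spec = spec, tiles = tiles)
}

# Clip a global mask to a half-open window, re-expressed in tile-local
# coordinates; NULL when the intersection is empty.
clip_mask_to_window <- function(mask, w) {
  b <- mask_bbox(mask)
  r0 <- max(b[1], w$row[1]); r1 <- min(b[3], w$row[2])
  c0 <- max(b[2], w$col[1]); c1 <- min(b[4], w$col[2])
  if (r1 <= r0 || c1 <= c0) return(NULL)
  px <- mask$pixels[(r0 - mask$offset[1] + 1L):(r1 - mask$offset[1]),
                    (c0 - mask$offset[2] + 1L):(c1 - mask$offset[2]),
                    drop = FALSE]
  if (!any(px)) return(NULL)
  mask_trim(new_mask(px, c(r0 - w$row[1], c0 - w$col[1]), mask$label))
}

#' Crop an annotated image into non-overlapping training tiles
#'
#' Tiles are a 512 px grid from the origin; images not divisible by the
#' tile size have their right/bottom remainder discarded. Each annotation
#' is clipped to every tile it intersects and re-expressed in tile-local
#' coordinates; clipped fragments smaller than `min_fragment_px` pixels are
#' dropped as unlabelable slivers.
#'
#' @param img An `eq_annotated_image` with ground truth.
#' @param tile_size Tile side in px (default 512).
#' @param min_fragment_px Minimum surviving fragment area (default 10).
#' @return List of `list(tile, masks, window)` entries, row-major.
#' @export
tile_training <- function(img, tile_size = TILE_SIZE_DEFAULT,
                          min_fragment_px = 10L) {
  stopifnot(inherits(img, "eq_annotated_image"))
  shape <- dim(img$image)
  if (any(shape < tile_size)) {
    stop(sprintf("images must be at least %d px per side", tile_size))
  }
  n_r <- shape[1] %/% tile_size
  n_c <- shape[2] %/% tile_size
  out <- list()
  for (i in seq_len(n_r) - 1L) for (j in seq_len(n_c) - 1L) {
    w <- list(row = c(i * tile_size, (i + 1L) * tile_size),
              col = c(j * tile_size, (j + 1L) * tile_size))
    masks <- list()
    for (m in img$ground_truth) {
      cm <- clip_mask_to_window(m, w)
      if (!is.null(cm) && mask_area(cm) >= min_fragment_px) {
        masks[[length(masks) + 1L]] <- cm
      }
    }
    out[[length(out) + 1L]] <- list(tile = crop_window(img$image, w),
                                    masks = masks, window = w)
  }
  out
}

#' Translate per-tile detections into global coordinates
#'
#' Pure offset arithmetic; nothing is dropped at this stage.
#'
#' @param tile_detections List (one entry per window, in `spec$windows`
#'   order) of per-tile `eq_detection` lists in tile-local coordinates.
#' @param spec The `eq_tile_spec` the tiles were cut with.
#' @return Single list of `eq_detection` in global coordinates.
#' @export
stitch <- function(tile_detections, spec) {
  stopifnot(length(tile_detections) == length(spec$windows))
  out <- list()
  for (k in seq_along(spec$windows)) {
    w <- spec$windows[[k]]
    for (d in tile_detections[[k]]) {
      b <- d$bbox
      if (b[3] > spec$tile_size || b[4] > spec$tile_size ||
          b[1] < 0 || b[2] < 0) {
        stop("detection exceeds its tile bounds (tile ", k, ")")
      }
      gm <- new_mask(d$mask$pixels,
                     d$mask$offset + c(w$row[1], w$col[1]), d$mask$label)
      out[[length(out) + 1L]] <- new_detection(gm, d$score)
    }
  }
  out
}

#' Remove implausibly sized detections
#'
#' The median m of mask pixel areas is taken over the full stitched image;
#' detections with area strictly below `0.10 * m` or strictly above
#' `5 * m` are removed as false positives. Areas exactly at either bound
#' are kept. Survivor order is preserved.
#'
#' @param dets List of `eq_detection`.
#' @param min_frac_of_median,max_mult_of_median Filter bounds (defaults
#'   0.10 and 5).
#' @return Filtered list of `eq_detection`.
#' @export
size_filter <- function(dets, min_frac_of_median = 0.10,
                        max_mult_of_median = 5) {
  if (length(dets) == 0L) return(dets)
  areas <- vapply(dets, function(d) mask_area(d$mask), integer(1))
  m <- stats::median(areas)
  keep <- areas >= min_frac_of_median * m & areas <= max_mult_of_median * m
  dets[keep]
}

# Half-open overlap-zone strips of a tile spec (regions covered by more
# than one window) as a list of bboxes.
overlap_zones <- function(spec) {
  strips <- function(windows, side) {
    z <- list()
    starts <- unique(vapply(windows, `[`, integer(1), 1L))
    ends <- unique(vapply(windows, `[`, integer(1), 2L))
    for (s in starts) for (e in ends) if (s < e) {
      covered <- sum(vapply(windows, function(w) s >= w[1] && e <= w[2],
                            logical(1)))
      if (covered >= 2L) z[[length(z) + 1L]] <- c(s, e)
    }
    z
  }
  rw <- unique(lapply(spec$windows, `[[`, "row"))
  cw <- unique(lapply(spec$windows, `[[`, "col"))
  zones <- list()
  for (z in strips(rw, spec$shape[1])) {
    zones[[length(zones) + 1L]] <- c(z[1], 0L, z[2], spec$shape[2])
  }
  for (z in strips(cw, spec$shape[2])) {
    zones[[length(zones) + 1L]] <- c(0L, z[1], spec$shape[1], z[2])
  }
  zones
}

#' Suppress duplicate detections in tile-overlap zones
#'
#' Among candidate pairs with mask IoU strictly above `iou_thr`, one member
#' per pair is dropped by a seeded coin flip, so double counting inside the
#' overlap strips between adjacent tiles is removed. Candidates are
#' detections whose bounding box intersects an overlap zone of the tiling;
#' detections wholly outside every overlap zone are never touched. Pairs
#' are visited greedily over candidates sorted by mask centroid (row, col),
#' making the result deterministic for a fixed seed, including chains of
#' more than two mutually overlapping detections.
#'
#' @param dets List of `eq_detection` in global coordinates.
#' @param spec The `eq_tile_spec` used for tiling (determines the overlap
#'   zones); pass `NULL` to consider every detection a candidate.
#' @param iou_thr Duplicate threshold (default 0.5, strict `>`).
#' @param seed Integer seed for the coin flips.
#' @return Filtered list of `eq_detection`, input order preserved.
#' @export
dedup_overlap <- function(dets, spec = NULL, iou_thr = 0.5, seed = 1L) {
  n <- length(dets)
  if (n < 2L) return(dets)
  if (!is.null(spec)) {
    zones <- overlap_zones(spec)
    cand <- vapply(dets, function(d) {
      any(vapply(zones, function(z) bbox_intersects(d$bbox, z), logical(1)))
    }, logical(1))
  } else {
    cand <- rep(TRUE, n)
  }
  idx <- which(cand)
  if (length(idx) < 2L) return(dets)
  cent <- t(vapply(dets[idx], function(d) mask_centroid(d$mask), numeric(2)))
  ord <- idx[order(cent[, 1], cent[, 2])]
  alive <- rep(TRUE, n)
  rng <- local_rng(seed)
  for (a_pos in seq_len(length(ord) - 1L)) {
    i <- ord[a_pos]
    if (!alive[i]) next
    for (b_pos in (a_pos + 1L):length(ord)) {
      j <- ord[b_pos]
      if (!alive[j] || !alive[i]) next
      if (!bbox_intersects(dets[[i]]$bbox, dets[[j]]$bbox)) next
      if (iou(dets[[i]]$mask, dets[[j]]$mask) > iou_thr) {
        if (rng() < 0.5) alive[i] <- FALSE else alive[j] <- FALSE
      }
      if (!alive[i]) break
    }
  }
  dets[alive]
}

# Seeded uniform RNG stream isolated from the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  function(n = 1L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    x <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    x
  }
}

# Deterministic sub-seed derivation so independent stages draw from
# independent streams of one user seed. Kept below 2^31 - 1.
split_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 1299721) %%
               2147483563)
}
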