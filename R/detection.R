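# Pluggable per-tile detector. The neural detector used in production runs
# (a Mask R-CNN variant tuned for small, dense, square toroidal objects) is
# captured here as a validated configuration schema; detection at desk
# scale runs through a deterministic classical baseline so the surrounding
# pipeline is fully testable without trained weights or a GPU.

#' Default detector configuration
#'
#' The validated configuration of the neural endosymbiont detector:
#' ResNet50 backbone feature maps from residual blocks 2-5, combined by a
#' feature pyramid network into maps of 16, 32, 64 and 128 px resolution;
#' square anchors of 32, 64, 128 and another 128 px (the 16 and 256 px
#' defaults are too small/large for these objects); up to 1000 region
#' proposals per 512 px tile; a 0.5 prediction-score threshold ahead of a
#' 4-layer x 256-channel convolutional mask head and a 2-layer x 1024-unit
#' fully connected box head; 40000 iterations of SGD with warmup + cosine
#' decay.
#'
#' @return A list of class `"eq_detector_config"`.
#' @export
default_detector_config <- function() {
  structure(list(
    backbone_blocks = c(2L, 3L, 4L, 5L),
    fpn_map_resolutions = c(16L, 32L, 64L, 128L),
    anchor_sizes = c(32L, 64L, 128L, 128L),
    aspect_ratio = 1,
    max_proposals_per_tile = 1000L,
    head_score_threshold = 0.5,
    mask_head = list(layers = 4L, channels = 256L),
    box_head = list(layers = 2L, units = 1024L),
    training = list(iterations = 40000L, optimizer = "sgd",
                    schedule = "warmup_cosine_decay")
  ), class = "eq_detector_config")
}

#' Validate a detector configuration
#'
#' Checks a configuration against the schema of the validated detector:
#' anchor list length must equal the FPN map count, anchors restricted to
#' the validated sizes (no 16 or 256 px anchors), square aspect ratio,
#' positive proposal cap, score threshold in (0, 1).
#'
#' @param config A detector configuration list.
#' @return `character(0)` when the configuration is valid, otherwise a
#'   character vector of violations.
#' @export
validate_detector_config <- function(config) {
  v <- character(0)
  need <- c("backbone_blocks", "fpn_map_resolutions", "anchor_sizes",
            "aspect_ratio", "max_proposals_per_tile", "head_score_threshold")
  miss <- setdiff(need, names(config))
  if (length(miss)) return(paste("missing field:", miss))
  if (length(config$anchor_sizes) != length(config$fpn_map_resolutions)) {
    v <- c(v, "anchor list length must equal the FPN feature-map count")
  }
  if (any(config$anchor_sizes %in% c(16L, 256L))) {
    v <- c(v, "anchors of 16 or 256 px are outside the validated range for these objects")
  }
  if (!identical(as.numeric(config$aspect_ratio), 1)) {
    v <- c(v, "aspect ratio must be 1 (square anchors)")
  }
  if (config$max_proposals_per_tile <= 0) {
    v <- c(v, "proposal cap must be positive")
  }
  if (config$head_score_threshold <= 0 || config$head_score_threshold >= 1) {
    v <- c(v, "score threshold must lie in (0, 1)")
  }
  if (!all(config$backbone_blocks %in% 2:5)) {
    v <- c(v, "backbone residual blocks must be drawn from 2..5")
  }
  v
}

#' Run a detector on one tile
#'
#' Enforces the per-tile detector contract regardless of the plugged-in
#' implementation: the tile is zero-padded to `tile_size` when smaller,
#' detections are cropped back to the unpadded extent, scores must lie in
#' `[0.01, 1]`, detections scoring below `head_score_threshold` are not
#' emitted, and at most `max_proposals_per_tile` detections (the
#' highest-scoring ones) are returned.
#'
#' @param tile Numeric tile matrix (carries its window as an attribute when
#'   produced by [tile_inference()]).
#' @param detector Function `(tile, config) -> list of eq_detection` in
#'   tile-local coordinates; defaults to [baseline_detect()].
#' @param config Detector configuration (default
#'   [default_detector_config()]).
#' @param tile_size Contracted tile side (default 512).
#' @return List of `eq_detection` in tile-local coordinates.
#' @export
detect_tile <- function(tile, detector = baseline_detect,
                        config = default_detector_config(),
                        tile_size = TILE_SIZE_DEFAULT) {
  orig <- dim(tile)
  w <- attr(tile, "window")
  if (any(orig < tile_size)) {
    padded <- matrix(0, tile_size, tile_size)
    padded[seq_len(orig[1]), seq_len(orig[2])] <- tile
    attr(padded, "window") <- w
    tile <- padded
  }
  dets <- tryCatch(detector(tile, config), error = function(e) {
    stop(sprintf("detector failed on tile [%s]: %s",
                 if (is.null(w)) "?" else paste(w$row[1], w$col[1], sep = ","),
                 conditionMessage(e)), call. = FALSE)
  })
  out <- list()
  for (d in dets) {
    if (d$score < 0.01 || d$score > 1) {
      stop("detector emitted a score outside [0.01, 1]")
    }
    if (d$score < config$head_score_threshold) next
    m <- d$mask
    b <- mask_bbox(m)
    if (b[3] > orig[1] || b[4] > orig[2]) {
      m <- clip_mask_to_window(m, list(row = c(0L, orig[1]),
                                       col = c(0L, orig[2])))
      if (is.null(m)) next
    }
    out[[length(out) + 1L]] <- new_detection(m, d$score)
  }
  if (length(out) > config$max_proposals_per_tile) {
    scores <- vapply(out, `[[`, numeric(1), "score")
    keep <- order(scores, decreasing = TRUE)[seq_len(config$max_proposals_per_tile)]
    out <- out[sort(keep)]
  }
  out
}

#' Deterministic classical baseline detector
#'
#' A classical-segmentation stand-in for the neural detector so the tiling,
#' stitching and evaluation stages can be exercised end to end:
#' difference-of-Gaussians band-pass smoothing isolates ring-scale
#' structure (cancelling large flat regions such as the nucleus), a global
#' Otsu threshold separates foreground, hole filling turns each annulus
#' into a solid blob, a distance-transform watershed splits touching
#' objects, and each resulting segment becomes one mask. The score is a
#' ring-likeness statistic - the normalized contrast between the segment's
#' outer annulus and its center, multiplied by circularity - affinely
#' mapped into `[0.01, 1]`. Fully deterministic: identical tiles give
#' bit-identical detections.
#'
#' @param tile Numeric matrix in `[0, 1]`.
#' @param config Detector configuration (only used for bookkeeping; the
#'   classical parameters live in `params`).
#' @param params List: `sigma_small`/`sigma_large` (band-pass radii, px),
#'   `min_area` (px), `watershed_tolerance`.
#' @return List of `eq_detection` in tile-local coordinates.
#' @export
baseline_detect <- function(tile, config = default_detector_config(),
                            params = list(sigma_small = 3, sigma_large = 12,
                                          min_area = 20,
                                          watershed_tolerance = 1)) {
  img <- EBImage::Image(t(tile))   # EBImage is column-major (x, y)
  dog <- EBImage::gblur(img, sigma = params$sigma_small) -
    EBImage::gblur(img, sigma = params$sigma_large)
  d <- EBImage::imageData(dog)
  rng <- range(d)
  if (diff(rng) < 1e-6) return(list())
  dn <- (d - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(dn), range = c(0, 1))
  bin <- EBImage::fillHull(EBImage::Image(dn > thr))
  if (sum(bin) == 0) return(list())
  dist <- EBImage::distmap(bin)
  seg <- EBImage::watershed(dist, tolerance = params$watershed_tolerance,
                            ext = 1)
  lab <- t(EBImage::imageData(seg))  # back to (row, col)
  if (max(lab) == 0) return(list())
  out <- list()
  for (k in unique(lab[lab > 0])) {
    px <- lab == k
    if (sum(px) < params$min_area) next
    m <- mask_trim(new_mask(px, c(0L, 0L), "buchnera"))
    out[[length(out) + 1L]] <- new_detection(m, ring_likeness(tile, m))
  }
  out
}

# Ring-likeness score: (annulus mean - center mean) / annulus mean, times
# circularity 4*pi*A/P^2, affinely mapped into [0.01, 1]. The 4-connected
# edge count overestimates the true perimeter of smooth shapes by ~4/pi,
# so it is corrected by pi/4 before the circularity ratio.
ring_likeness <- function(tile, mask) {
  idx <- which(mask$pixels, arr.ind = TRUE)
  cen <- colMeans(idx)
  d <- sqrt((idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2)
  dmax <- max(d)
  vals <- tile[cbind(idx[, 1] + mask$offset[1], idx[, 2] + mask$offset[2])]
  if (dmax < 2) return(0.01)
  ring <- vals[d >= 0.6 * dmax]
  hole <- vals[d <= 0.35 * dmax]
  contrast <- if (length(ring) == 0 || length(hole) == 0 ||
                  mean(ring) <= 0) 0 else
    max(0, (mean(ring) - mean(hole)) / mean(ring))
  per <- mask_perimeter(mask) * pi / 4
  circ <- min(1, 4 * pi * sum(mask$pixels) / per^2)
  raw <- sqrt(max(0, contrast * circ))
  0.01 + 0.99 * min(1, max(0, raw))
}

# 4-connected boundary length (count of exposed pixel edges).
mask_perimeter <- function(mask) {
  p <- mask$pixels
  pad <- matrix(FALSE, nrow(p) + 2L, ncol(p) + 2L)
  pad[2:(nrow(p) + 1L), 2:(ncol(p) + 1L)] <- p
  core <- pad[2:(nrow(p) + 1L), 2:(ncol(p) + 1L)]
  sum(core & !pad[1:nrow(p), 2:(ncol(p) + 1L)]) +
    sum(core & !pad[3:(nrow(p) + 2L), 2:(ncol(p) + 1L)]) +
    sum(core & !pad[2:(nrow(p) + 1L), 1:ncol(p)]) +
    sum(core & !pad[2:(nrow(p) + 1L), 3:(ncol(p) + 2L)])
}

#' Default augmentation specification
#'
#' Photometric and geometric training-set augmentation: brightness and
#' contrast factors drawn uniformly from `[0.6, 1.8]`, isotropic scale from
#' `[0.5, 1]`, and independent horizontal/vertical flips each with
#' probability 0.5.
#'
#' @param brightness_range,contrast_range,scale_range Ordered length-2
#'   numeric ranges.
#' @param horizontal_flip,vertical_flip Flip probabilities.
#' @param seed Integer seed.
#' @return A list of class `"eq_augmentation_spec"`.
#' @export
augmentation_spec <- function(brightness_range = c(0.6, 1.8),
                              contrast_range = c(0.6, 1.8),
                              scale_range = c(0.5, 1),
                              horizontal_flip = 0.5, vertical_flip = 0.5,
                              seed = 1L) {
  stopifnot(brightness_range[1] <= brightness_range[2],
            contrast_range[1] <= contrast_range[2],
            scale_range[1] <= scale_range[2], scale_range[1] > 0)
  structure(list(brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 scale_range = scale_range,
                 horizontal_flip = horizontal_flip,
                 vertical_flip = vertical_flip,
                 seed = as.integer(seed)),
            class = "eq_augmentation_spec")
}

#' Draw one set of augmentation factors
#'
#' @param spec An `eq_augmentation_spec`.
#' @param index Draw index; `(seed, index)` determines the factors.
#' @return List: `brightness`, `contrast`, `scale`, `hflip`, `vflip`.
#' @export
draw_augmentation <- function(spec, index = 1L) {
  rng <- local_rng(split_seed(spec$seed, index))
  u <- rng(5L)
  list(brightness = spec$brightness_range[1] +
         u[1] * diff(spec$brightness_range),
       contrast = spec$contrast_range[1] + u[2] * diff(spec$contrast_range),
       scale = spec$scale_range[1] + u[3] * diff(spec$scale_range),
       hflip = u[4] < spec$horizontal_flip,
       vflip = u[5] < spec$vertical_flip)
}

#' Augment a training sample
#'
#' Applies one seeded draw of photometric (brightness, mean-pivoted
#' contrast) and geometric (scale, flips) factors; the identical geometric
#' transform is applied to the image and every mask, so mask pixel counts
#' are preserved under flips. Downscaled images are zero-padded back to
#' their original size; masks scaled to nothing are dropped.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param masks List of `eq_mask` aligned with the image.
#' @param spec An `eq_augmentation_spec`.
#' @param index Draw index (see [draw_augmentation()]).
#' @param factors Optional explicit factor list overriding the seeded draw.
#' @return List with `image`, `masks`, `factors`.
#' @export
augment_sample <- function(image, masks = list(), spec = augmentation_spec(),
                           index = 1L, factors = NULL) {
  f <- if (is.null(factors)) draw_augmentation(spec, index) else factors
  shape <- dim(image)
  img <- image * f$brightness
  img <- mean(img) + f$contrast * (img - mean(img))
  frames <- lapply(masks, mask_to_frame, image_shape = shape)
  if (f$scale != 1) {
    nr <- max(1L, round(shape[1] * f$scale))
    nc <- max(1L, round(shape[2] * f$scale))
    img_s <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(img)),
                                                  w = nc, h = nr)))
    img <- matrix(0, shape[1], shape[2])
    img[seq_len(nr), seq_len(nc)] <- img_s
    frames <- lapply(frames, function(fr) {
      fs <- t(EBImage::imageData(EBImage::resize(
        EBImage::Image(t(fr * 1)), w = nc, h = nr, filter = "none"))) > 0.5
      out <- matrix(FALSE, shape[1], shape[2])
      out[seq_len(nr), seq_len(nc)] <- fs
      out
    })
  }
  if (f$hflip) {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    frames <- lapply(frames, function(fr) fr[, rev(seq_len(ncol(fr))), drop = FALSE])
  }
  if (f$vflip) {
    img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    frames <- lapply(frames, function(fr) fr[rev(seq_len(nrow(fr))), , drop = FALSE])
  }
  labels <- vapply(masks, `[[`, character(1), "label")
  out_masks <- list()
  for (i in seq_along(frames)) {
    m <- frame_to_mask(frames[[i]], labels[i])
    if (!is.null(m)) out_masks[[length(out_masks) + 1L]] <- m
  }
  list(image = pmin(pmax(img, 0), 1), masks = out_masks, factors = f)
}

#' Oracle detector that echoes known ground truth
#'
#' Builds a detector (for pipeline tests) that, for each tile, returns
#' every ground-truth mask whose full extent lies inside the tile window,
#' re-expressed in tile-local coordinates. Objects inside overlap zones are
#' returned by several tiles and exercise the duplicate suppression. Scores
#' are distinct, high, and deterministic per object.
#'
#' @param ground_truth List of `eq_mask` in global coordinates.
#' @return A detector function for [detect_tile()].
#' @export
truth_detector <- function(ground_truth) {
  n <- length(ground_truth)
  scores <- if (n) 0.9 + 0.1 * (seq_len(n) / (n + 1)) else numeric(0)
  function(tile, config) {
    w <- attr(tile, "window")
    if (is.null(w)) stop("truth detector requires tiles carrying their window")
    out <- list()
    for (i in seq_len(n)) {
      b <- mask_bbox(ground_truth[[i]])
      if (b[1] >= w$row[1] && b[3] <= w$row[2] &&
          b[2] >= w$col[1] && b[4] <= w$col[2]) {
        m <- ground_truth[[i]]
        lm <- new_mask(m$pixels, m$offset - c(w$row[1], w$col[1]), m$label)
        out[[length(out) + 1L]] <- new_detection(lm, scores[i])
      }
    }
    out
  }
}
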