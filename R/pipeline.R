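# End-to-end orchestration: overlapping tiling -> per-tile detection ->
# stitching -> median-size filter -> overlap deduplication -> result file.
# Curation is a batch edit file (removals + added polygons) rather than an
# interactive GUI, so curated analyses stay scriptable and testable.

#' Default pipeline configuration
#'
#' Single configuration covering tiling, the detector schema, augmentation,
#' the backend filters, and the analysis significance level.
#'
#' @return Nested list with components `tiling` (`tile_size`, `overlap`),
#'   `detector` ([default_detector_config()]), `augmentation`
#'   ([augmentation_spec()]), `filters` (`min_frac_of_median`,
#'   `max_mult_of_median`, `dedup_iou`), `alpha`, `seed`.
#' @export
default_config <- function() {
  list(tiling = list(tile_size = TILE_SIZE_DEFAULT,
                     overlap = TILE_OVERLAP_DEFAULT),
       detector = default_detector_config(),
       augmentation = augmentation_spec(),
       filters = list(min_frac_of_median = 0.10, max_mult_of_median = 5,
                      dedup_iou = 0.5),
       alpha = 0.05, seed = 1L)
}

#' Load a configuration file
#'
#' JSON (or YAML when the `yaml` package is installed) with any subset of
#' the [default_config()] keys; unspecified values keep their defaults.
#'
#' @param path Config file path.
#' @return Config list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  cfg <- default_config()
  merge_in <- function(base, upd) {
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]])) {
        merge_in(base[[k]], upd[[k]])
      } else upd[[k]]
    }
    base
  }
  merge_in(cfg, user)
}

#' Run the full detection pipeline on one image
#'
#' Stages, in order: overlapping inference tiling; the detector on every
#' tile; stitching into global coordinates; removal of detections smaller
#' than 10% or larger than 5x the median mask size; seeded IoU > 0.5
#' duplicate suppression restricted to tile-overlap zones. Per-stage object
#' counts are logged (via `message()`) when `verbose`. A pure function of
#' (image, detector, config, seed): repeated runs are identical.
#'
#' @param img An `eq_annotated_image` (or intensity matrix).
#' @param detector Detector function for [detect_tile()]; default
#'   [baseline_detect()].
#' @param config Pipeline config ([default_config()]).
#' @param seed Seed for the duplicate-suppression coin flips; defaults to
#'   `config$seed`.
#' @param verbose Log per-stage counts.
#' @return An `eq_result`.
#' @export
run_pipeline <- function(img, detector = baseline_detect,
                         config = default_config(), seed = NULL,
                         verbose = FALSE) {
  if (is.matrix(img)) img <- new_annotated_image(img)
  if (is.null(seed)) seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  tl <- tile_inference(img, config$tiling$tile_size, config$tiling$overlap)
  say("tiling: %d tiles of %d px (overlap %d)", length(tl$tiles),
      config$tiling$tile_size, config$tiling$overlap)
  per_tile <- lapply(tl$tiles, function(tile) {
    detect_tile(tile, detector, config$detector,
                tile_size = config$tiling$tile_size)
  })
  n_raw <- sum(lengths(per_tile))
  say("detection: %d raw detections (%.1fs)", n_raw, proc.time()[3] - t0)
  dets <- stitch(per_tile, tl$spec)
  say("stitch: %d detections in global coordinates", length(dets))
  dets <- size_filter(dets, config$filters$min_frac_of_median,
                      config$filters$max_mult_of_median)
  say("size filter: %d detections retained", length(dets))
  dets <- dedup_overlap(dets, tl$spec, iou_thr = config$filters$dedup_iou,
                        seed = seed)
  say("dedup: %d final detections (%.1fs total)", length(dets),
      proc.time()[3] - t0)
  new_result(img$identifier, dim(img$image), dets,
             pixel_per_micron = img$pixel_per_micron)
}

#' Construct an edit file
#'
#' Non-interactive curation: indices of detections to remove (type I
#' errors) and polygon rings to add as new masks (type II errors).
#'
#' @param image_id Image the edits apply to.
#' @param removals Integer vector of 1-based detection indices.
#' @param additions List of two-column `(x, y)` polygon vertex matrices.
#' @param scores Scores for added masks (recycled; default 1, the score of
#'   a human-confirmed object).
#' @return List of class `"eq_edits"`.
#' @export
new_edits <- function(image_id, removals = integer(0), additions = list(),
                      scores = 1) {
  structure(list(image_id = image_id, removals = as.integer(removals),
                 additions = additions,
                 scores = rep_len(scores, length(additions))),
            class = "eq_edits")
}

#' Read / write edit files (JSON)
#' @param path File path.
#' @return For `read_edits`, an `eq_edits`.
#' @export
read_edits <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  adds <- lapply(doc$additions, function(p) {
    matrix(as.numeric(unlist(p)), ncol = 2, byrow = TRUE)
  })
  new_edits(doc$image_id, as.integer(unlist(doc$removals)), adds,
            scores = if (is.null(doc$scores)) 1 else as.numeric(unlist(doc$scores)))
}

#' @rdname read_edits
#' @param edits An `eq_edits`.
#' @export
write_edits <- function(edits, path) {
  doc <- list(image_id = edits$image_id, removals = edits$removals,
              additions = lapply(edits$additions, function(v) {
                lapply(seq_len(nrow(v)), function(i) as.numeric(v[i, ]))
              }),
              scores = edits$scores)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Apply curation edits to a result
#'
#' Removals are applied before additions, so removal indices always refer
#' to the uncurated result; added polygons are rasterized under the
#' standard fill rule and must lie within the image. The output holds
#' `n - |removals| + |additions|` masks.
#'
#' @param result An `eq_result`.
#' @param edits An `eq_edits` referencing `result$image_id`.
#' @return The curated `eq_result`.
#' @export
apply_edits <- function(result, edits) {
  if (!identical(edits$image_id, result$image_id)) {
    stop("edit file targets image '", edits$image_id, "', result is '",
         result$image_id, "'")
  }
  n <- length(result$detections)
  if (length(edits$removals) &&
      (any(edits$removals < 1L) || any(edits$removals > n))) {
    stop("removal index out of range 1..", n)
  }
  dets <- result$detections
  if (length(edits$removals)) dets <- dets[-edits$removals]
  for (i in seq_along(edits$additions)) {
    m <- polygon_to_mask(edits$additions[[i]], result$shape)
    dets[[length(dets) + 1L]] <- new_detection(m, edits$scores[i])
  }
  new_result(result$image_id, result$shape, dets,
             pixel_per_micron = result$pixel_per_micron)
}
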