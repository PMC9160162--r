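# Per-bacteriocyte morphometrics. Whole-cell and nuclear areas are measured
# externally (e.g. in FIJI) and supplied in square microns; detections come
# from the (possibly curated) pipeline result in pixels.

#' Construct a per-cell record
#'
#' @param cell_area_um2 Whole-cell area, square microns.
#' @param nucleus_area_um2 Nuclear area, square microns
#'   (`0 < nucleus < cell`).
#' @param pixel_per_micron Image scale, pixels per micron.
#' @param detections List of `eq_detection` (final, post-curation), or
#'   `NULL` when `areas_px`/`union_px` are supplied directly.
#' @param timepoint Ordered label (e.g. `"day3"`).
#' @param cell_id Identifier.
#' @param areas_px,union_px Optional precomputed per-object pixel areas and
#'   union pixel area, used when mask rasters are not carried (e.g. large
#'   simulated cohorts).
#' @return An object of class `"eq_cell_record"`.
#' @export
new_cell_record <- function(cell_area_um2, nucleus_area_um2, pixel_per_micron,
                            detections = NULL, timepoint = NA_character_,
                            cell_id = "cell", areas_px = NULL,
                            union_px = NULL) {
  if (!(cell_area_um2 > nucleus_area_um2 && nucleus_area_um2 > 0)) {
    stop("require cell area > nucleus area > 0")
  }
  if (pixel_per_micron <= 0) stop("pixel_per_micron must be positive")
  if (is.null(detections) && is.null(areas_px)) {
    stop("supply detections or precomputed pixel areas")
  }
  structure(list(cell_id = cell_id, timepoint = timepoint,
                 cell_area_um2 = cell_area_um2,
                 nucleus_area_um2 = nucleus_area_um2,
                 pixel_per_micron = pixel_per_micron,
                 detections = detections, areas_px = areas_px,
                 union_px = union_px),
            class = "eq_cell_record")
}

#' Convert a pixel area to square microns
#'
#' With the scale expressed as pixels per micron (the default orientation),
#' one square micron covers `ratio^2` pixels, so
#' `area_um2 = area_px / ratio^2`. Set `orientation = "um_per_px"` when the
#' supplied ratio is microns per pixel, in which case the area is
#' multiplied by `ratio^2`.
#'
#' @param area_px Area in pixels (squared pixels).
#' @param ratio Positive scale factor.
#' @param orientation `"px_per_um"` (default) or `"um_per_px"`.
#' @return Area in square microns.
#' @export
px_area_to_um2 <- function(area_px, ratio,
                           orientation = c("px_per_um", "um_per_px")) {
  if (ratio <= 0) stop("scale ratio must be positive")
  orientation <- match.arg(orientation)
  if (orientation == "px_per_um") area_px / ratio^2 else area_px * ratio^2
}

#' Per-cell endosymbiont metrics
#'
#' Computes, per bacteriocyte: (1) cytoplasm area = whole cell area -
#' nuclear area (square microns); (2) density = object count / cytoplasm
#' area (objects per square micron); (3) per-object areas converted from
#' pixels to square microns; (4) per-object "diameter" = sqrt(area / pi)
#' in microns - note this expression is geometrically the radius of the
#' equal-area circle, but the field name follows the established metric
#' name; (5) occupied cytoplasm fraction = (union area of all object
#' masks, i.e. summed areas minus every overlap counted once) / cytoplasm
#' area, reported both as a fraction and as a percentage.
#'
#' @param rec An `eq_cell_record`.
#' @return A list of class `"eq_cell_metrics"`: `n_buchnera`,
#'   `cytoplasm_area_um2`, `density_per_um2`, `buchnera_areas_um2`,
#'   `buchnera_diameters_um`, `occupied_fraction`, `occupied_pct`, plus the
#'   record's id/timepoint.
#' @export
compute_cell_metrics <- function(rec) {
  stopifnot(inherits(rec, "eq_cell_record"))
  cyto <- rec$cell_area_um2 - rec$nucleus_area_um2
  if (cyto <= 0) stop("cytoplasm area must be positive")
  if (!is.null(rec$detections)) {
    areas_px <- vapply(rec$detections, function(d) mask_area(d$mask),
                       integer(1))
    uni_px <- union_area(lapply(rec$detections, `[[`, "mask"))
  } else {
    areas_px <- rec$areas_px
    uni_px <- if (!is.null(rec$union_px)) rec$union_px else sum(areas_px)
  }
  n <- length(areas_px)
  areas_um2 <- px_area_to_um2(areas_px, rec$pixel_per_micron)
  frac <- px_area_to_um2(uni_px, rec$pixel_per_micron) / cyto
  structure(list(cell_id = rec$cell_id, timepoint = rec$timepoint,
                 n_buchnera = n, cytoplasm_area_um2 = cyto,
                 density_per_um2 = n / cyto,
                 buchnera_areas_um2 = areas_um2,
                 buchnera_diameters_um = sqrt(areas_um2 / pi),
                 occupied_fraction = frac, occupied_pct = 100 * frac),
            class = "eq_cell_metrics")
}

#' Trim outliers by absolute z-score
#'
#' Z-scores are computed once from the sample mean and sample (n-1)
#' standard deviation of the full input; values with `|z|` strictly
#' greater than `z_max` are removed in a single pass. With zero standard
#' deviation nothing is removed.
#'
#' @param values Numeric vector, length `>= 2`.
#' @param z_max Cutoff (default 3; strict `>`).
#' @return List with `kept`, `removed`, and the logical `keep` index.
#' @export
trim_outliers_z <- function(values, z_max = 3) {
  stopifnot(length(values) >= 2L)
  s <- stats::sd(values)
  if (is.na(s) || s == 0) {
    return(list(kept = values, removed = values[0],
                keep = rep(TRUE, length(values))))
  }
  z <- (values - mean(values)) / s
  keep <- abs(z) <= z_max
  list(kept = values[keep], removed = values[!keep], keep = keep)
}

#' Tidy morphometrics tables for a set of cells
#'
#' Applies [compute_cell_metrics()] to each record and assembles (i) one
#' row per cell and (ii) a long table of per-object areas/diameters.
#' Outlier trimming follows the analysis convention: cell-level metrics are
#' screened across all cells jointly, object-level areas within each
#' timepoint, both by absolute z-score > `z_max` in a single pass.
#'
#' @param records List of `eq_cell_record`.
#' @param trim Logical; apply z-score trimming (default TRUE).
#' @param z_max Cutoff for trimming (default 3).
#' @return List of class `"eq_morphometrics"`: `cells` (data.frame),
#'   `objects` (data.frame), `trimmed` (counts removed).
#' @export
morphometrics_table <- function(records, trim = TRUE, z_max = 3) {
  mets <- lapply(records, compute_cell_metrics)
  cells <- do.call(rbind, lapply(mets, function(m) {
    data.frame(cell_id = m$cell_id, timepoint = m$timepoint,
               n_buchnera = m$n_buchnera,
               cytoplasm_area_um2 = m$cytoplasm_area_um2,
               density_per_um2 = m$density_per_um2,
               occupied_fraction = m$occupied_fraction,
               occupied_pct = m$occupied_pct,
               stringsAsFactors = FALSE)
  }))
  objects <- do.call(rbind, lapply(mets, function(m) {
    if (m$n_buchnera == 0L) return(NULL)
    data.frame(cell_id = m$cell_id, timepoint = m$timepoint,
               area_um2 = m$buchnera_areas_um2,
               diameter_um = m$buchnera_diameters_um,
               stringsAsFactors = FALSE)
  }))
  trimmed <- c(cells = 0L, objects = 0L)
  if (trim && nrow(cells) >= 2L) {
    keep <- rep(TRUE, nrow(cells))
    for (col in c("n_buchnera", "density_per_um2", "occupied_fraction",
                  "cytoplasm_area_um2")) {
      keep <- keep & trim_outliers_z(cells[[col]], z_max)$keep
    }
    trimmed["cells"] <- sum(!keep)
    cells <- cells[keep, , drop = FALSE]
  }
  if (trim && !is.null(objects)) {
    keep <- rep(TRUE, nrow(objects))
    for (tp in unique(objects$timepoint)) {
      i <- if (is.na(tp)) is.na(objects$timepoint) else
        !is.na(objects$timepoint) & objects$timepoint == tp
      if (sum(i) >= 2L) {
        keep[i] <- trim_outliers_z(objects$area_um2[i], z_max)$keep
      }
    }
    trimmed["objects"] <- sum(!keep)
    objects <- objects[keep, , drop = FALSE]
  }
  structure(list(cells = cells, objects = objects, trimmed = trimmed),
            class = "eq_morphometrics")
}

#' Metrics from result files plus a cell-measurement table
#'
#' @param results List of `eq_result` (one per cell image).
#' @param measurements data.frame with columns `cell_id`, `timepoint`,
#'   `cell_area_um2`, `nucleus_area_um2`, and optionally
#'   `pixel_per_micron` (falls back to the result file's value). `cell_id`
#'   must match the results' `image_id`s.
#' @param ... Passed to [morphometrics_table()].
#' @return An `eq_morphometrics`.
#' @export
morphometrics_from_results <- function(results, measurements, ...) {
  ids <- vapply(results, `[[`, character(1), "image_id")
  records <- lapply(seq_along(results), function(i) {
    row <- measurements[measurements$cell_id == ids[i], , drop = FALSE]
    if (nrow(row) != 1L) stop("no unique measurement row for image ", ids[i])
    ppm <- if ("pixel_per_micron" %in% names(row)) row$pixel_per_micron else
      results[[i]]$pixel_per_micron
    new_cell_record(row$cell_area_um2, row$nucleus_area_um2, ppm,
                    detections = results[[i]]$detections,
                    timepoint = as.character(row$timepoint),
                    cell_id = ids[i])
  })
  morphometrics_table(records, ...)
}
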