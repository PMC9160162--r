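# Synthetic DAPI-like scenes with exact ground truth: densely packed
# toroidal objects (bright annulus, dim center) inside an elliptical cell
# with an elliptical nucleus, rendered on a dark background with Gaussian
# noise. Ground-truth masks are the filled disks - the object's full
# extent, as an annotator outlining whole cells would draw them - while the
# torus appearance is a rendering property only.

#' Specify a synthetic scene
#'
#' Defaults emulate the geometry of a bacteriocyte micrograph: objects of
#' roughly 1 micron radius imaged at 10 px per micron (so a 20 px object
#' diameter, sensibly covered by a 32 px smallest detector anchor), packed
#' inside an elliptical cell with a central nucleus.
#'
#' @param side Image side in px (`>= 512`).
#' @param pixel_per_micron Scale (default 10).
#' @param n_objects Number of objects to place.
#' @param radius_mean_um,radius_sd_um Object radius distribution, microns.
#' @param annulus_fraction Fraction of the radius occupied by the bright
#'   ring (default 0.5; the inner `1 - annulus_fraction` is the dim hole).
#' @param max_overlap Maximum allowed pairwise disk-overlap fraction
#'   (intersection area over the smaller disk's area; 0 = disjoint).
#' @param cell_axes_frac,nucleus_axes_frac Ellipse semi-axes as fractions
#'   of the side.
#' @param background,ring_level,hole_level,nucleus_level Intensity levels
#'   in `[0, 1]`.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed; all randomness in the scene flows from it via
#'   deterministic sub-streams.
#' @return A list of class `"eq_scene_spec"`.
#' @export
scene_spec <- function(side = 1024L, pixel_per_micron = 10, n_objects = 80L,
                       radius_mean_um = 1, radius_sd_um = 0.15,
                       annulus_fraction = 0.5, max_overlap = 0,
                       cell_axes_frac = c(0.44, 0.38),
                       nucleus_axes_frac = c(0.13, 0.11),
                       background = 0.05, ring_level = 0.85,
                       hole_level = 0.25, nucleus_level = 0.7,
                       noise_sd = 0.02, seed = 1L) {
  stopifnot(side >= 512L, pixel_per_micron > 0, radius_mean_um > 0,
            annulus_fraction > 0, annulus_fraction < 1,
            max_overlap >= 0, max_overlap <= 1)
  structure(list(side = as.integer(side),
                 pixel_per_micron = pixel_per_micron,
                 n_objects = as.integer(n_objects),
                 radius_mean_um = radius_mean_um,
                 radius_sd_um = radius_sd_um,
                 annulus_fraction = annulus_fraction,
                 max_overlap = max_overlap,
                 cell_axes_frac = cell_axes_frac,
                 nucleus_axes_frac = nucleus_axes_frac,
                 background = background, ring_level = ring_level,
                 hole_level = hole_level, nucleus_level = nucleus_level,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "eq_scene_spec")
}

# Area of intersection of two disks divided by the smaller disk's area.
disk_overlap_fraction <- function(c1, r1, c2, r2) {
  d <- sqrt(sum((c1 - c2)^2))
  if (d >= r1 + r2) return(0)
  rmin <- min(r1, r2)
  if (d <= abs(r1 - r2)) return(1)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  (a1 + a2 - a3) / (pi * rmin^2)
}

in_ellipse <- function(p, center, axes) {
  sum(((p - center) / axes)^2) <= 1
}

# Place n disk centers/radii inside the cell ellipse, outside the nucleus,
# honoring the pairwise overlap cap, by seeded rejection sampling.
place_objects <- function(spec, rng) {
  centers <- matrix(NA_real_, spec$n_objects, 2)
  radii <- numeric(spec$n_objects)
  cell_c <- rep(spec$side / 2, 2)
  cell_a <- spec$cell_axes_frac * spec$side
  nuc_c <- cell_c
  nuc_a <- spec$nucleus_axes_frac * spec$side
  max_tries <- 2000L * spec$n_objects
  placed <- 0L; tries <- 0L
  while (placed < spec$n_objects) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("object placement failed; lower n_objects or raise max_overlap")
    }
    u <- rng(3L)
    r_um <- spec$radius_mean_um + spec$radius_sd_um * stats::qnorm(
      0.001 + 0.998 * u[3])
    r <- max(2, r_um * spec$pixel_per_micron)
    p <- c(cell_c[1] + (2 * u[1] - 1) * cell_a[1],
           cell_c[2] + (2 * u[2] - 1) * cell_a[2])
    # object fully inside the cell ellipse (shrunk by its radius), and its
    # center clear of the nucleus by its radius
    if (!in_ellipse(p, cell_c, pmax(cell_a - r, 1))) next
    if (in_ellipse(p, nuc_c, nuc_a + r)) next
    ok <- TRUE
    if (placed > 0L) {
      for (q in seq_len(placed)) {
        if (disk_overlap_fraction(p, r, centers[q, ], radii[q]) >
            spec$max_overlap) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    placed <- placed + 1L
    centers[placed, ] <- p
    radii[placed] <- r
  }
  list(centers = centers, radii = radii, cell_center = cell_c,
       cell_axes = cell_a, nucleus_center = nuc_c, nucleus_axes = nuc_a)
}

# Regular polygon approximating a circle; rasterizes to the disk mask.
circle_polygon <- function(center_rc, radius, n_vertices = 64L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(x = center_rc[2] + radius * cos(th),
        y = center_rc[1] + radius * sin(th))
}

#' Generate a synthetic annotated scene
#'
#' Places `n_objects` disks by seeded rejection sampling (inside the cell
#' ellipse, outside the nucleus, honoring the pairwise overlap cap), builds
#' one filled-disk ground-truth mask per object by rasterizing a 64-gon
#' circle polygon, and renders each object as a bright annulus with a dim
#' central hole over the nucleus and background, plus Gaussian noise.
#' Deterministic for a fixed seed: the same spec yields a bit-identical
#' image and masks.
#'
#' @param spec An `eq_scene_spec`.
#' @param render Logical; when `FALSE` the intensity image is skipped (a
#'   zero raster is attached) and only geometry/ground truth is built.
#' @return List of class `"eq_scene"`: `annotated`
#'   (`eq_annotated_image` with ground truth), `record`
#'   (`eq_cell_record` carrying the true cell/nucleus areas and the
#'   ground-truth masks as perfect detections), `polygons` (the circle
#'   polygons), `centers`, `radii_px`.
#' @export
generate_scene <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "eq_scene_spec"))
  rng <- local_rng(split_seed(spec$seed, 1L))
  geo <- place_objects(spec, rng)
  shape <- c(spec$side, spec$side)
  masks <- list(); polys <- list()
  for (i in seq_len(spec$n_objects)) {
    v <- circle_polygon(geo$centers[i, ], geo$radii[i])
    polys[[i]] <- v
    masks[[i]] <- polygon_to_mask(v, shape)
  }
  img <- matrix(spec$background, shape[1], shape[2])
  if (render) {
    rr <- matrix(rep(seq_len(shape[1]) - 0.5, shape[2]), shape[1])
    cc <- matrix(rep(seq_len(shape[2]) - 0.5, each = shape[1]), shape[1])
    nuc <- ((rr - geo$nucleus_center[1]) / geo$nucleus_axes[1])^2 +
      ((cc - geo$nucleus_center[2]) / geo$nucleus_axes[2])^2 <= 1
    img[nuc] <- spec$nucleus_level
    for (i in seq_len(spec$n_objects)) {
      m <- masks[[i]]
      idx <- which(m$pixels, arr.ind = TRUE)
      gr <- idx[, 1] - 0.5 + m$offset[1]
      gc <- idx[, 2] - 0.5 + m$offset[2]
      d <- sqrt((gr - geo$centers[i, 1])^2 + (gc - geo$centers[i, 2])^2)
      hole_r <- (1 - spec$annulus_fraction) * geo$radii[i]
      val <- ifelse(d <= hole_r, spec$hole_level, spec$ring_level)
      img[cbind(idx[, 1] + m$offset[1], idx[, 2] + m$offset[2])] <-
        pmax(img[cbind(idx[, 1] + m$offset[1], idx[, 2] + m$offset[2])], val)
    }
    if (spec$noise_sd > 0) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      set.seed(split_seed(spec$seed, 3L))
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                          shape[1], shape[2])
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
    img <- pmin(pmax(img, 0), 1)
  }
  ppm <- spec$pixel_per_micron
  cell_area_um2 <- pi * prod(geo$cell_axes) / ppm^2
  nuc_area_um2 <- pi * prod(geo$nucleus_axes) / ppm^2
  annotated <- new_annotated_image(img, ground_truth = masks,
                                   pixel_per_micron = ppm,
                                   identifier = sprintf("scene_seed%d", spec$seed))
  dets <- lapply(seq_along(masks), function(i) {
    new_detection(masks[[i]], 0.9 + 0.1 * i / (length(masks) + 1))
  })
  record <- new_cell_record(cell_area_um2, nuc_area_um2, ppm,
                            detections = dets,
                            cell_id = annotated$identifier)
  structure(list(annotated = annotated, record = record, polygons = polys,
                 centers = geo$centers, radii_px = geo$radii,
                 spec = spec),
            class = "eq_scene")
}

#' Degrade ground truth into imperfect predictions
#'
#' Controlled corruption of a ground-truth mask list for exercising the
#' evaluation stage: drops `floor(drop_frac * n)` objects (seeded choice),
#' translates survivors by a seeded integer jitter of at most `jitter_px`
#' per axis, and appends `n_clutter` spurious disk masks placed so their
#' bounding boxes avoid every ground-truth box (guaranteeing IoU 0 with
#' truth). Surviving-truth scores are drawn from `score_model$tp` and
#' clutter scores from `score_model$clutter` (uniform within each band),
#' clipped to `[0.01, 1]`.
#'
#' @param gts List of ground-truth `eq_mask`.
#' @param drop_frac Fraction of objects to drop, in `[0, 1]`.
#' @param jitter_px Maximum absolute per-axis translation (integer px).
#' @param n_clutter Number of spurious masks to append.
#' @param image_shape Integer `c(rows, cols)` bounding all masks.
#' @param score_model List with `tp` and `clutter` ranges.
#' @param clutter_radius Radius of clutter disks in px.
#' @param seed Integer seed.
#' @return List of `eq_detection`.
#' @export
degrade_truth <- function(gts, drop_frac = 0, jitter_px = 0L, n_clutter = 0L,
                          image_shape, score_model = list(tp = c(0.7, 1),
                                                          clutter = c(0.05, 0.4)),
                          clutter_radius = 5, seed = 1L) {
  stopifnot(drop_frac >= 0, drop_frac <= 1)
  n <- length(gts)
  rng <- local_rng(split_seed(seed, 7L))
  n_drop <- floor(drop_frac * n)
  keep <- seq_len(n)
  if (n_drop > 0L) {
    drop <- order(rng(n))[seq_len(n_drop)]
    keep <- setdiff(keep, drop)
  }
  out <- list()
  for (i in keep) {
    m <- gts[[i]]
    if (jitter_px > 0L) {
      dj <- floor(rng(2L) * (2 * jitter_px + 1)) - jitter_px
      m2 <- mask_translate(m, dj[1], dj[2], image_shape)
      if (!is.null(m2)) m <- m2
    }
    s <- score_model$tp[1] + rng(1L) * diff(score_model$tp)
    out[[length(out) + 1L]] <- new_detection(m, min(1, max(0.01, s)))
  }
  gt_boxes <- lapply(gts, mask_bbox)
  added <- 0L; tries <- 0L
  while (added < n_clutter) {
    tries <- tries + 1L
    if (tries > 200L * max(1L, n_clutter)) {
      stop("could not place clutter clear of ground truth")
    }
    u <- rng(2L)
    cen <- c(clutter_radius + u[1] * (image_shape[1] - 2 * clutter_radius),
             clutter_radius + u[2] * (image_shape[2] - 2 * clutter_radius))
    m <- polygon_to_mask(circle_polygon(cen, clutter_radius), image_shape,
                         label = "clutter")
    b <- mask_bbox(m)
    if (any(vapply(gt_boxes, function(g) bbox_intersects(b, g), logical(1)))) next
    s <- score_model$clutter[1] + rng(1L) * diff(score_model$clutter)
    out[[length(out) + 1L]] <- new_detection(m, min(1, max(0.01, s)))
    added <- added + 1L
  }
  out
}

#' Generate a developmental cohort of synthetic cells
#'
#' Stands in for a multi-timepoint developmental study: per timepoint,
#' `n_cells` cells are generated with object counts drawn
#' Poisson around a per-timepoint expectation (the base count times that
#' timepoint's `count_multiplier`) and radii shifted by `radius_multiplier`.
#' Geometry is exact (disk placement and analytic areas); intensity
#' rendering is skipped by default so large cohorts stay cheap, which is
#' all the morphometrics and statistics stages need.
#'
#' @param timepoints Character vector of timepoint labels (`>= 2`).
#' @param n_cells_per_timepoint Cells per timepoint.
#' @param base_spec An `eq_scene_spec` providing the shared geometry.
#' @param effect List with numeric vectors `count_multiplier` and
#'   `radius_multiplier`, one entry per timepoint (default all 1: the null
#'   model).
#' @param seed Integer seed.
#' @param rasterize Logical; when `TRUE` each cell's record carries full
#'   mask detections (slow for big cohorts), otherwise analytic disk areas.
#' @return List of class `"eq_cohort"`: `records` (list of
#'   `eq_cell_record`), `cells` (data.frame summary with the true
#'   parameters), `timepoints`.
#' @export
generate_cohort <- function(timepoints, n_cells_per_timepoint = 16L,
                            base_spec = scene_spec(), effect = NULL,
                            seed = 1L, rasterize = FALSE) {
  stopifnot(length(timepoints) >= 2L)
  k <- length(timepoints)
  if (is.null(effect)) {
    effect <- list(count_multiplier = rep(1, k), radius_multiplier = rep(1, k))
  }
  stopifnot(length(effect$count_multiplier) == k,
            length(effect$radius_multiplier) == k)
  records <- list(); rows <- list(); cell_i <- 0L
  for (t in seq_len(k)) {
    for (cidx in seq_len(n_cells_per_timepoint)) {
      cell_i <- cell_i + 1L
      sub_seed <- split_seed(seed, cell_i)
      rng <- local_rng(split_seed(sub_seed, 11L))
      lambda <- base_spec$n_objects * effect$count_multiplier[t]
      n_obj <- stats::qpois(rng(1L), lambda)
      sp <- base_spec
      sp$n_objects <- max(1L, as.integer(n_obj))
      sp$radius_mean_um <- base_spec$radius_mean_um * effect$radius_multiplier[t]
      sp$seed <- sub_seed
      ppm <- sp$pixel_per_micron
      if (rasterize) {
        scn <- generate_scene(sp, render = FALSE)
        rec <- scn$record
        rec$timepoint <- timepoints[t]
        rec$cell_id <- sprintf("tp%s_cell%02d", timepoints[t], cidx)
      } else {
        geo <- place_objects(sp, local_rng(split_seed(sub_seed, 1L)))
        # pixel-exact disk areas are within a pixel-quantization ripple of
        # pi r^2; the analytic value is the truth the generator bookkeeps
        areas_px <- pi * geo$radii^2
        rec <- new_cell_record(pi * prod(geo$cell_axes) / ppm^2,
                               pi * prod(geo$nucleus_axes) / ppm^2, ppm,
                               areas_px = areas_px,
                               union_px = sum(areas_px) -
                                 total_pairwise_overlap(geo, sp$max_overlap),
                               timepoint = timepoints[t],
                               cell_id = sprintf("tp%s_cell%02d",
                                                 timepoints[t], cidx))
      }
      records[[cell_i]] <- rec
      rows[[cell_i]] <- data.frame(
        cell_id = rec$cell_id, timepoint = timepoints[t],
        n_true = sp$n_objects, lambda = lambda,
        radius_mean_um = sp$radius_mean_um, stringsAsFactors = FALSE)
    }
  }
  structure(list(records = records, cells = do.call(rbind, rows),
                 timepoints = timepoints),
            class = "eq_cohort")
}

# Analytic total pairwise-overlap area (zero when placement is disjoint).
total_pairwise_overlap <- function(geo, max_overlap) {
  if (max_overlap == 0) return(0)
  tot <- 0
  n <- nrow(geo$centers)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    f <- disk_overlap_fraction(geo$centers[i, ], geo$radii[i],
                               geo$centers[j, ], geo$radii[j])
    tot <- tot + f * pi * min(geo$radii[i], geo$radii[j])^2
  }
  tot
}

#' Write a scene to disk (PNG + COCO truth + measurement CSV row)
#'
#' @param scene An `eq_scene`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- scene$annotated$identifier
  png_path <- file.path(dir, paste0(id, ".png"))
  write_image(scene$annotated, png_path)
  shape <- dim(scene$annotated$image)
  doc <- list(
    images = list(list(id = 1L, file_name = basename(png_path),
                       height = shape[1], width = shape[2])),
    annotations = lapply(seq_along(scene$polygons), function(i) {
      m <- scene$annotated$ground_truth[[i]]; b <- mask_bbox(m)
      list(id = i, image_id = 1L, category_id = 1L,
           segmentation = list(as.numeric(t(scene$polygons[[i]]))),
           bbox = as.numeric(c(b[2], b[1], b[4] - b[2], b[3] - b[1])),
           area = mask_area(m), iscrowd = 0L)
    }),
    categories = list(list(id = 1L, name = "buchnera",
                           supercategory = "endosymbiont")))
  coco_path <- file.path(dir, paste0(id, "_truth.json"))
  write_coco(doc, coco_path)
  rec <- scene$record
  csv_path <- file.path(dir, paste0(id, "_measurements.csv"))
  utils::write.csv(data.frame(cell_id = rec$cell_id,
                              timepoint = rec$timepoint,
                              cell_area_um2 = rec$cell_area_um2,
                              nucleus_area_um2 = rec$nucleus_area_um2,
                              pixel_per_micron = rec$pixel_per_micron),
                   csv_path, row.names = FALSE)
  invisible(c(png = png_path, coco = coco_path, csv = csv_path))
}
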