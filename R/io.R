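# Readers/writers: PNG images, labelme JSON, COCO JSON, and the pipeline's
# JSON "result" file. Lossy image formats are refused; PNG/TIFF only.

MIN_IMAGE_SIDE <- 512L

#' Construct an annotated image
#'
#' @param image Numeric matrix in `[0, 1]` (rows x cols), side `>= 512` px.
#' @param ground_truth List of `eq_mask`, all within the image bounds.
#' @param pixel_per_micron Positive scale factor (pixels per micron).
#' @param identifier Image id string.
#' @param timepoint Optional ordered label (e.g. `"day3"`).
#' @return An object of class `"eq_annotated_image"`.
#' @export
new_annotated_image <- function(image, ground_truth = list(),
                                pixel_per_micron = 1, identifier = "image",
                                timepoint = NULL) {
  if (!is.matrix(image)) stop("image must be a 2-D intensity matrix")
  if (nrow(image) < MIN_IMAGE_SIDE || ncol(image) < MIN_IMAGE_SIDE) {
    stop(sprintf("images must be at least %d x %d pixels", MIN_IMAGE_SIDE,
                 MIN_IMAGE_SIDE))
  }
  if (pixel_per_micron <= 0) stop("pixel_per_micron must be positive")
  shape <- dim(image)
  for (m in ground_truth) {
    b <- mask_bbox(m)
    if (b[3] > shape[1] || b[4] > shape[2]) {
      stop("ground-truth mask extends outside the image")
    }
  }
  structure(list(image = image, ground_truth = ground_truth,
                 pixel_per_micron = pixel_per_micron,
                 identifier = identifier, timepoint = timepoint),
            class = "eq_annotated_image")
}

#' Read a grayscale micrograph
#'
#' Accepts PNG (and TIFF when the `tiff` package is installed); lossy
#' formats such as JPEG are refused because compression artifacts corrupt
#' segmentation. Images smaller than 512 px on a side are rejected.
#'
#' @param path File path.
#' @param pixel_per_micron Scale factor attached to the returned object.
#' @param identifier Image id; defaults to the file name without extension.
#' @param timepoint Optional timepoint label.
#' @return An `eq_annotated_image` with no ground truth.
#' @export
read_image <- function(path, pixel_per_micron = 1, identifier = NULL,
                       timepoint = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg", "gif", "webp")) {
    stop("lossy image formats are not supported; use PNG or TIFF")
  }
  raw <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: .", ext)
  }
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] >= 2L && !all(raw[, , 1] == raw[, , 2])) {
      stop("expected a single-channel grayscale image; select the channel upstream")
    }
    raw <- raw[, , 1]
  }
  if (is.null(identifier)) identifier <- tools::file_path_sans_ext(basename(path))
  new_annotated_image(raw, pixel_per_micron = pixel_per_micron,
                      identifier = identifier, timepoint = timepoint)
}

#' Write a grayscale image to PNG
#' @param image Numeric matrix in `[0, 1]` or an `eq_annotated_image`.
#' @param path Output path.
#' @export
write_image <- function(image, path) {
  if (inherits(image, "eq_annotated_image")) image <- image$image
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read labelme polygon annotations
#'
#' One mask per polygon shape; labels preserved; non-polygon shape types
#' are skipped with a warning. The image raster itself is not loaded (the
#' `imageData` field, when present, is ignored).
#'
#' @param path Path to a labelme JSON file.
#' @return List with `identifier`, `height`, `width`, `masks` (list of
#'   `eq_mask`), and `polygons` (the original vertex matrices, parallel to
#'   `masks`).
#' @export
read_labelme <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$imageHeight) || is.null(doc$imageWidth)) {
    stop("labelme file lacks imageHeight/imageWidth: ", path)
  }
  shape <- c(as.integer(doc$imageHeight), as.integer(doc$imageWidth))
  masks <- list(); polys <- list()
  for (sh in doc$shapes) {
    if (!identical(sh$shape_type, "polygon")) {
      warning("skipping non-polygon shape of type '", sh$shape_type, "'")
      next
    }
    v <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    m <- polygon_to_mask(v, shape, label = sh$label)
    masks[[length(masks) + 1L]] <- m
    polys[[length(polys) + 1L]] <- v
  }
  id <- if (!is.null(doc$imagePath)) {
    tools::file_path_sans_ext(basename(doc$imagePath))
  } else {
    tools::file_path_sans_ext(basename(path))
  }
  list(identifier = id, height = shape[1], width = shape[2],
       masks = masks, polygons = polys)
}

#' Convert labelme files to a single COCO document
#'
#' Produces one COCO JSON with `images`, `annotations` (polygon
#' segmentation + bounding box + rasterized pixel area) and one category
#' per distinct label. Annotation ids are unique and contiguous from 1.
#'
#' @param labelme_files Character vector of labelme JSON paths (may be
#'   empty, yielding a valid COCO document with zero images).
#' @param out_path Optional path; when given the document is also written.
#' @return The COCO document as a list.
#' @export
labelme_to_coco <- function(labelme_files, out_path = NULL) {
  parsed <- lapply(labelme_files, read_labelme)
  ids <- vapply(parsed, `[[`, character(1), "identifier")
  if (anyDuplicated(ids)) stop("duplicate image identifiers: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  labels <- sort(unique(unlist(lapply(parsed, function(p) {
    vapply(p$masks, `[[`, character(1), "label")
  }))))
  if (length(labels) == 0L) labels <- "buchnera"
  categories <- lapply(seq_along(labels), function(i) {
    list(id = i, name = labels[i], supercategory = "endosymbiont")
  })
  images <- list(); annotations <- list(); ann_id <- 0L
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    images[[i]] <- list(id = i, file_name = paste0(p$identifier, ".png"),
                        height = p$height, width = p$width)
    for (j in seq_along(p$masks)) {
      ann_id <- ann_id + 1L
      m <- p$masks[[j]]; v <- p$polygons[[j]]; b <- mask_bbox(m)
      annotations[[ann_id]] <- list(
        id = ann_id, image_id = i,
        category_id = match(m$label, labels),
        segmentation = list(as.numeric(t(v))),
        bbox = as.numeric(c(b[2], b[1], b[4] - b[2], b[3] - b[1])),
        area = mask_area(m), iscrowd = 0L)
    }
  }
  doc <- list(images = images, annotations = annotations,
              categories = categories)
  if (!is.null(out_path)) write_coco(doc, out_path)
  doc
}

#' Read a COCO JSON document
#'
#' Validates that every annotation's `image_id` refers to a listed image
#' and every `category_id` to a listed category.
#'
#' @param path Path to COCO JSON.
#' @return The document as a list (`images`, `annotations`, `categories`).
#' @export
read_coco <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$images)) doc$images <- list()
  if (is.null(doc$annotations)) doc$annotations <- list()
  if (is.null(doc$categories)) doc$categories <- list()
  img_ids <- vapply(doc$images, function(x) as.integer(x$id), integer(1))
  cat_ids <- vapply(doc$categories, function(x) as.integer(x$id), integer(1))
  for (a in doc$annotations) {
    if (!(as.integer(a$image_id) %in% img_ids)) {
      stop("annotation ", a$id, " references unknown image_id ", a$image_id)
    }
    if (length(cat_ids) && !(as.integer(a$category_id) %in% cat_ids)) {
      stop("annotation ", a$id, " references unknown category_id ", a$category_id)
    }
  }
  doc
}

#' Write a COCO document
#' @param doc COCO document list as produced by [labelme_to_coco()] or
#'   [read_coco()].
#' @param path Output path.
#' @export
write_coco <- function(doc, path) {
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Masks from a COCO document
#'
#' Rasterizes every polygon segmentation for one image id under the same
#' pixel-center-inside rule used for labelme input.
#'
#' @param doc COCO document list.
#' @param image_id Integer image id.
#' @return List of `eq_mask`.
#' @export
coco_masks <- function(doc, image_id) {
  img <- NULL
  for (im in doc$images) if (as.integer(im$id) == image_id) img <- im
  if (is.null(img)) stop("image_id ", image_id, " not present")
  shape <- c(as.integer(img$height), as.integer(img$width))
  labels <- vapply(doc$categories, function(x) as.character(x$name), character(1))
  ids <- vapply(doc$categories, function(x) as.integer(x$id), integer(1))
  out <- list()
  for (a in doc$annotations) {
    if (as.integer(a$image_id) != image_id) next
    seg <- as.numeric(unlist(a$segmentation[[1]]))
    v <- matrix(seg, ncol = 2, byrow = TRUE)
    lab <- labels[match(as.integer(a$category_id), ids)]
    out[[length(out) + 1L]] <- polygon_to_mask(v, shape, label = lab)
  }
  out
}

#' Construct a result file object
#'
#' The final, possibly curated, output of the pipeline for one image: the
#' coordinates of every retained object mask. Masks are stored pixel-exactly
#' as per-row runs so that reading a written file reproduces the original
#' pixel sets bit for bit.
#'
#' @param image_id Image identifier string.
#' @param shape Integer `c(rows, cols)` of the source image.
#' @param detections List of `eq_detection` (global coordinates).
#' @param pixel_per_micron Scale factor recorded with the result.
#' @return An object of class `"eq_result"`.
#' @export
new_result <- function(image_id, shape, detections = list(),
                       pixel_per_micron = 1) {
  shape <- as.integer(shape)
  for (d in detections) {
    b <- d$bbox
    if (b[1] < 0 || b[2] < 0 || b[3] > shape[1] || b[4] > shape[2]) {
      stop("detection mask falls outside the image bounds")
    }
  }
  structure(list(image_id = image_id, shape = shape,
                 pixel_per_micron = pixel_per_micron,
                 detections = detections),
            class = "eq_result")
}

#' @export
print.eq_result <- function(x, ...) {
  cat(sprintf("<result '%s': %d masks, %dx%d px, %.3g px/um>\n", x$image_id,
              length(x$detections), x$shape[1], x$shape[2],
              x$pixel_per_micron))
  invisible(x)
}

mask_to_runs <- function(mask) {
  runs <- list()
  for (r in seq_len(nrow(mask$pixels))) {
    v <- mask$pixels[r, ]
    rle_v <- rle(v)
    ends <- cumsum(rle_v$lengths)
    starts <- ends - rle_v$lengths + 1L
    for (k in which(rle_v$values)) {
      runs[[length(runs) + 1L]] <-
        c(r - 1L, starts[k] - 1L, rle_v$lengths[k])
    }
  }
  runs
}

runs_to_mask <- function(runs, offset, label) {
  runs <- lapply(runs, function(x) as.integer(unlist(x)))
  nr <- max(vapply(runs, `[`, integer(1), 1L)) + 1L
  nc <- max(vapply(runs, function(x) x[2] + x[3], integer(1)))
  px <- matrix(FALSE, nr, nc)
  for (x in runs) px[x[1] + 1L, (x[2] + 1L):(x[2] + x[3])] <- TRUE
  mask_trim(new_mask(px, as.integer(offset), label))
}

#' Write a result file
#' @param result An `eq_result`.
#' @param path Output path (JSON).
#' @export
write_result <- function(result, path) {
  masks <- lapply(result$detections, function(d) {
    m <- mask_trim(d$mask)
    list(label = m$label, score = d$score,
         offset = as.integer(m$offset),
         runs = mask_to_runs(m))
  })
  doc <- list(image_id = result$image_id,
              shape = as.integer(result$shape),
              pixel_per_micron = result$pixel_per_micron,
              masks = masks)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a result file
#' @param path Path to a result JSON written by [write_result()].
#' @return An `eq_result`.
#' @export
read_result <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  shape <- as.integer(unlist(doc$shape))
  dets <- lapply(doc$masks, function(mk) {
    m <- runs_to_mask(mk$runs, unlist(mk$offset), mk$label)
    new_detection(m, mk$score)
  })
  new_result(doc$image_id, shape, dets,
             pixel_per_micron = as.numeric(doc$pixel_per_micron))
}

#' COCO bbox to half-open BBox and back
#'
#' COCO boxes are `[x, y, w, h]` with `x` along columns and `y` along rows;
#' the internal representation is half-open `[row_min, row_max) x
#' [col_min, col_max)`. The two conversions are exact inverses on integer
#' boxes.
#'
#' @param xywh Numeric `[x, y, w, h]`.
#' @return An `eq_bbox`.
#' @export
coco_bbox_to_bbox <- function(xywh) {
  new_bbox(xywh[2], xywh[1], xywh[2] + xywh[4], xywh[1] + xywh[3])
}

#' @rdname coco_bbox_to_bbox
#' @param bbox An `eq_bbox`.
#' @export
bbox_to_coco_bbox <- function(bbox) {
  as.numeric(c(bbox[2], bbox[1], bbox[4] - bbox[2], bbox[3] - bbox[1]))
}
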