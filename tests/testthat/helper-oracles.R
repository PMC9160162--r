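# Brute-force oracles kept independent of the implementation under test.

# Global pixel set of a mask as "row:col" strings.
pixel_set <- function(mask) {
  idx <- which(mask$pixels, arr.ind = TRUE)
  paste(idx[, 1] - 1L + mask$offset[1], idx[, 2] - 1L + mask$offset[2],
        sep = ":")
}

oracle_iou <- function(a, b) {
  sa <- pixel_set(a); sb <- pixel_set(b)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

oracle_union_area <- function(masks) {
  length(unique(unlist(lapply(masks, pixel_set))))
}

# Winding-angle point-in-polygon test (different algorithm from the
# implementation's even-odd crossing rule).
oracle_point_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(vertices[i, 2] - py, vertices[i, 1] - px)
    a2 <- atan2(vertices[j, 2] - py, vertices[j, 1] - px)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    total <- total + d
  }
  abs(total) > pi   # winding number != 0
}

# Plain trapezoid over (recall, precision) points plus the (0, 1) anchor.
oracle_trapezoid_ap <- function(recall, precision) {
  ord <- order(recall, precision)
  r <- c(0, recall[ord]); p <- c(1, precision[ord])
  area <- 0
  for (i in seq_len(length(r) - 1L)) {
    area <- area + (r[i + 1] - r[i]) * (p[i] + p[i + 1]) / 2
  }
  area
}

# Axis-aligned rectangle mask: h x w of TRUE at global (r0, c0).
rect_mask <- function(r0, c0, h, w, label = "buchnera") {
  new_mask(matrix(TRUE, h, w), c(r0, c0), label)
}

# Random blob mask near (r0, c0) for property tests.
random_mask <- function(rng_fun, r0, c0, max_side = 12L) {
  h <- 2L + floor(rng_fun(1) * max_side)
  w <- 2L + floor(rng_fun(1) * max_side)
  px <- matrix(rng_fun(h * w) < 0.7, h, w)
  if (!any(px)) px[1, 1] <- TRUE
  new_mask(px, c(r0, c0))
}

# Seeded runif stream for helpers (isolated from the global RNG).
make_rng <- function(seed) {
  env <- new.env()
  local({set.seed(seed); env$state <- .Random.seed})
  function(n = 1L) {
    old <- .Random.seed
    assign(".Random.seed", env$state, envir = globalenv())
    x <- runif(n)
    env$state <- .Random.seed
    assign(".Random.seed", old, envir = globalenv())
    x
  }
}

# Minimal labelme document writer for fixtures.
write_labelme_fixture <- function(path, image_name, height, width, shapes) {
  doc <- list(version = "5.0.1", flags = structure(list(), names = character(0)),
              shapes = shapes, imagePath = image_name,
              imageData = NULL, imageHeight = height, imageWidth = width)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  path
}

labelme_polygon <- function(label, vertices) {
  list(label = label,
       points = lapply(seq_len(nrow(vertices)),
                       function(i) as.numeric(vertices[i, ])),
       group_id = NULL, shape_type = "polygon",
       flags = structure(list(), names = character(0)))
}
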