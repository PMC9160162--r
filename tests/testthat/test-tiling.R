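test_that("inference tiling yields the documented window grids", {
  expect_length(tile_spec(c(2048, 2048))$windows, 25)   # 5 x 5
  expect_length(tile_spec(c(1024, 1024))$windows, 9)    # 3 x 3
  expect_length(tile_spec(c(512, 512))$windows, 1)
  expect_error(tile_spec(c(500, 2048)), "at least 512")

  # stride = 512 - 85 = 427; last window clamped to the edge
  sp <- tile_spec(c(2048, 2048))
  starts <- sort(unique(vapply(sp$windows, function(w) w$row[1], integer(1))))
  expect_equal(starts, c(0L, 427L, 854L, 1281L, 1536L))
})

test_that("inference windows cover every pixel with >= 85 px interior overlaps", {
  for (side in c(512L, 700L, 1024L, 2048L)) {
    sp <- tile_spec(c(side, side))
    covered <- rep(0L, side)
    starts <- sort(unique(vapply(sp$windows, function(w) w$row[1], integer(1))))
    for (s in starts) covered[(s + 1):(s + 512)] <- covered[(s + 1):(s + 512)] + 1L
    expect_true(all(covered >= 1L))
    if (length(starts) > 1) {
      gaps <- diff(starts)
      expect_true(all(512L - gaps >= 85L))   # adjacent windows share >= overlap
    }
  }
})

test_that("training tiling is a non-overlapping grid with per-tile annotations", {
  rng <- make_rng(5150)
  img_px <- matrix(0, 1024, 1024)
  gt <- list(rect_mask(100, 100, 12, 12),    # wholly inside tile (0,0)
             rect_mask(508, 700, 12, 12),    # straddles the row boundary
             rect_mask(250, 509, 3, 12))     # straddles the col boundary: 9 px left, 27 px right
  img <- new_annotated_image(img_px, gt, identifier = "train")
  tiles <- tile_training(img)
  expect_length(tiles, 4)
  expect_length(tile_training(new_annotated_image(matrix(0, 2048, 2048))), 16)

  # annotation wholly inside one tile appears exactly once, pixel-identical
  hits <- which(vapply(tiles, function(t) length(t$masks) > 0, logical(1)))
  m1 <- tiles[[1]]$masks[[1]]
  expect_equal(m1$offset, c(100L, 100L))
  expect_equal(mask_area(m1), 144L)

  # straddling annotation is clipped into both adjacent tiles
  frag_areas <- integer(0)
  for (t in tiles) for (m in t$masks) frag_areas <- c(frag_areas, mask_area(m))
  expect_true(48L %in% frag_areas)  # 4 rows x 12 cols in the upper tile
  expect_true(96L %in% frag_areas)  # 8 rows x 12 cols in the lower tile

  # fragment smaller than 10 px is dropped (mask 3: 9 px in tile (0,0))
  expect_false(9L %in% frag_areas)
  expect_true(27L %in% frag_areas)  # its 12x3 - 9 = 27 px remainder survives
})

test_that("stitching translates tile-local detections by the window origin", {
  sp <- tile_spec(c(1024, 1024))
  k <- which(vapply(sp$windows, function(w) {
    w$row[1] == 427L && w$col[1] == 0L
  }, logical(1)))
  per_tile <- rep(list(list()), length(sp$windows))
  per_tile[[k]] <- list(new_detection(rect_mask(10, 10, 5, 5), 0.9))
  out <- stitch(per_tile, sp)
  expect_length(out, 1)
  expect_equal(out[[1]]$mask$offset, c(437L, 10L))
  expect_equal(out[[1]]$score, 0.9)

  expect_length(stitch(rep(list(list()), length(sp$windows)), sp), 0)

  per_tile[[k]] <- list(new_detection(rect_mask(508, 508, 10, 10), 0.9))
  expect_error(stitch(per_tile, sp), "exceeds")
})

test_that("size filter removes outliers by the median rule with inclusive bounds", {
  mk <- function(area, r0) new_detection(rect_mask(r0, 0, 1, area), 0.9)
  dets <- c(lapply(1:9, function(i) mk(100, 2 * i)), list(mk(5, 40)))
  kept <- size_filter(dets)
  expect_length(kept, 9)
  expect_true(all(vapply(kept, function(d) mask_area(d$mask), integer(1)) == 100))

  same <- lapply(1:5, function(i) mk(60, 3 * i))
  expect_length(size_filter(same), 5)

  # exactly 0.10 * median and exactly 5 * median are kept (strict removal)
  areas <- c(10, rep(100, 8), 500)   # median 100
  dets2 <- lapply(seq_along(areas), function(i) mk(areas[i], 2 * i))
  expect_length(size_filter(dets2), 10)
  expect_length(size_filter(c(dets2, list(mk(9, 90)))), 10)  # 9 < 0.1 * 100 goes
  expect_length(size_filter(list()), 0)
})

test_that("overlap dedup drops one of each high-IoU pair, deterministically", {
  sp <- tile_spec(c(1024, 1024))
  # centered on the row overlap strip [427, 512)
  twin_a <- new_detection(rect_mask(430, 200, 10, 10), 0.92)
  twin_b <- new_detection(rect_mask(430, 200, 10, 10), 0.93)
  low_a <- new_detection(rect_mask(450, 600, 10, 10), 0.9)
  low_b <- new_detection(rect_mask(455, 600, 10, 10), 0.9)  # IoU = 5/15 = 1/3
  far <- new_detection(rect_mask(700, 700, 10, 10), 0.9)
  dets <- list(twin_a, twin_b, low_a, low_b, far)

  out <- dedup_overlap(dets, sp, seed = 11)
  expect_length(out, 4)
  areas_left <- sum(vapply(out, function(d) d$mask$offset[2] == 200, logical(1)))
  expect_equal(areas_left, 1)  # exactly one twin survives

  # pair at IoU 1/3 < 0.5 both kept
  expect_equal(sum(vapply(out, function(d) d$mask$offset[2] == 600, logical(1))), 2)

  # determinism for a fixed seed
  out2 <- dedup_overlap(dets, sp, seed = 11)
  expect_identical(lapply(out, function(d) d$mask$offset),
                   lapply(out2, function(d) d$mask$offset))

  # identical duplicates outside every overlap zone are left alone
  iso_a <- new_detection(rect_mask(100, 100, 10, 10), 0.9)
  iso_b <- new_detection(rect_mask(100, 100, 10, 10), 0.9)
  expect_length(dedup_overlap(list(iso_a, iso_b), sp, seed = 1), 2)
})

test_that("after dedup no surviving candidate pair exceeds the IoU bound", {
  rng <- make_rng(88)
  for (rep in 1:10) {
    dets <- lapply(1:30, function(i) {
      r0 <- floor(rng(1) * 60); c0 <- floor(rng(1) * 60)
      new_detection(rect_mask(r0, c0, 10, 10), 0.5 + 0.5 * i / 31)
    })
    out <- dedup_overlap(dets, spec = NULL, seed = rep)
    if (length(out) >= 2) {
      for (i in 1:(length(out) - 1)) for (j in (i + 1):length(out)) {
        expect_lte(iou(out[[i]]$mask, out[[j]]$mask), 0.5)
      }
    }
  }
})

test_that("chained duplicates collapse to a single survivor", {
  sp <- tile_spec(c(1024, 1024))
  quad <- lapply(1:4, function(i) new_detection(rect_mask(460, 460, 12, 12),
                                                0.9 + 0.01 * i))
  expect_length(dedup_overlap(quad, sp, seed = 3), 1)
})
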