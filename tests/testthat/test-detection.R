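test_that("detector configuration schema accepts the validated defaults and flags deviations", {
  cfg <- default_detector_config()
  expect_length(validate_detector_config(cfg), 0)
  expect_equal(cfg$anchor_sizes, c(32L, 64L, 128L, 128L))
  expect_equal(cfg$fpn_map_resolutions, c(16L, 32L, 64L, 128L))
  expect_equal(cfg$max_proposals_per_tile, 1000L)
  expect_equal(cfg$head_score_threshold, 0.5)
  expect_equal(cfg$training$iterations, 40000L)

  bad <- cfg; bad$anchor_sizes <- c(16L, 64L, 128L, 128L)
  expect_match(validate_detector_config(bad), "16 or 256", all = FALSE)
  bad2 <- cfg; bad2$aspect_ratio <- 2
  expect_match(validate_detector_config(bad2), "aspect ratio", all = FALSE)
  bad3 <- cfg; bad3$anchor_sizes <- c(32L, 64L, 128L)
  expect_match(validate_detector_config(bad3), "length", all = FALSE)
})

test_that("blank tiles yield no detections and identical tiles identical output", {
  expect_length(detect_tile(matrix(0, 512, 512)), 0)

  spc <- scene_spec(side = 512, n_objects = 10, noise_sd = 0, seed = 7)
  scn <- generate_scene(spc)
  tile <- tile_inference(scn$annotated)$tiles[[1]]
  d1 <- detect_tile(tile)
  d2 <- detect_tile(tile)
  expect_identical(d1, d2)
})

test_that("baseline detector finds well-separated toroids exactly", {
  spc <- scene_spec(side = 512, n_objects = 10, noise_sd = 0, seed = 7)
  scn <- generate_scene(spc)
  dets <- detect_tile(tile_inference(scn$annotated)$tiles[[1]])
  expect_length(dets, 10)
  m <- match_detections(dets, scn$annotated$ground_truth)
  expect_equal(nrow(m$tp), 10)
  expect_length(m$fp, 0)
  prf <- precision_recall_f1(m, 10)
  expect_equal(as.numeric(prf[c("precision", "recall")]), c(1, 1))
})

test_that("baseline splits two toroids with controlled overlap", {
  spc <- scene_spec(side = 512, n_objects = 12, noise_sd = 0,
                    max_overlap = 0.3, seed = 2)
  scn <- generate_scene(spc)
  dets <- detect_tile(tile_inference(scn$annotated)$tiles[[1]])
  m <- match_detections(dets, scn$annotated$ground_truth)
  expect_equal(nrow(m$tp), 12)
  expect_length(m$fp, 0)
})

test_that("detect_tile enforces the score contract and proposal cap", {
  flood_detector <- function(tile, config) {
    lapply(1:1500, function(i) {
      r0 <- ((i - 1) %% 50) * 10
      c0 <- ((i - 1) %/% 50) * 16
      new_detection(rect_mask(r0, c0, 4, 4), 0.5 + 0.5 * i / 1501)
    })
  }
  out <- detect_tile(matrix(0, 512, 512), flood_detector)
  expect_length(out, 1000)
  # the retained 1000 are the highest-scoring candidates
  expect_gte(min(vapply(out, `[[`, numeric(1), "score")),
             0.5 + 0.5 * 500 / 1501)

  low_detector <- function(tile, config) {
    list(new_detection(rect_mask(0, 0, 4, 4), 0.49),
         new_detection(rect_mask(20, 20, 4, 4), 0.51))
  }
  out2 <- detect_tile(matrix(0, 512, 512), low_detector)
  expect_length(out2, 1)   # sub-threshold detection not emitted
  expect_equal(out2[[1]]$score, 0.51)

  bad_detector <- function(tile, config) {
    d <- list(mask = rect_mask(0, 0, 4, 4), bbox = mask_bbox(rect_mask(0, 0, 4, 4)),
              score = 2)
    class(d) <- "eq_detection"
    list(d)
  }
  expect_error(detect_tile(matrix(0, 512, 512), bad_detector), "0.01")

  fail_detector <- function(tile, config) stop("GPU on fire")
  expect_error(detect_tile(matrix(0, 512, 512), fail_detector),
               "detector failed.*GPU on fire")
})

test_that("augmentation factors respect their declared ranges over many draws", {
  spec <- augmentation_spec(seed = 42)
  draws <- vapply(seq_len(10000), function(i) {
    f <- draw_augmentation(spec, i)
    c(f$brightness, f$contrast, f$scale)
  }, numeric(3))
  expect_gte(min(draws[1, ]), 0.6); expect_lte(max(draws[1, ]), 1.8)
  expect_gte(min(draws[2, ]), 0.6); expect_lte(max(draws[2, ]), 1.8)
  expect_gte(min(draws[3, ]), 0.5); expect_lte(max(draws[3, ]), 1.0)
  # the draws actually explore the ranges
  expect_lt(min(draws[1, ]), 0.7); expect_gt(max(draws[1, ]), 1.7)
})

test_that("identity augmentation and double flips leave the sample unchanged", {
  rng <- make_rng(9)
  img <- matrix(rng(512 * 512), 512, 512)
  masks <- list(rect_mask(10, 20, 8, 6), rect_mask(100, 400, 10, 10))

  unit <- augment_sample(img, masks, factors = list(
    brightness = 1, contrast = 1, scale = 1, hflip = FALSE, vflip = FALSE))
  expect_equal(unit$image, img)
  expect_identical(lapply(unit$masks, pixel_set), lapply(masks, pixel_set))

  flip <- list(brightness = 1, contrast = 1, scale = 1, hflip = TRUE, vflip = TRUE)
  once <- augment_sample(img, masks, factors = flip)
  twice <- augment_sample(once$image, once$masks, factors = flip)
  expect_equal(twice$image, img)
  expect_identical(lapply(twice$masks, pixel_set), lapply(masks, pixel_set))

  # isometries preserve mask pixel counts
  expect_equal(vapply(once$masks, mask_area, integer(1)),
               vapply(masks, mask_area, integer(1)))
})

test_that("seeded augmentation is reproducible and photometrics act as declared", {
  spec <- augmentation_spec(seed = 3)
  img <- matrix(seq(0, 1, length.out = 512 * 512), 512, 512)
  a <- augment_sample(img, list(), spec, index = 5)
  b <- augment_sample(img, list(), spec, index = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$factors, b$factors)

  # brightness-only factor scales intensities before clipping
  br <- augment_sample(matrix(0.25, 512, 512), list(), factors = list(
    brightness = 1.6, contrast = 1, scale = 1, hflip = FALSE, vflip = FALSE))
  expect_equal(unique(as.vector(br$image)), 0.4)
})
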