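test_that("scene generation places the requested objects deterministically", {
  spc <- scene_spec(side = 512, n_objects = 50, seed = 21)
  scn <- generate_scene(spc)
  expect_length(scn$annotated$ground_truth, 50)
  expect_s3_class(scn$annotated, "eq_annotated_image")
  expect_s3_class(scn$record, "eq_cell_record")

  scn2 <- generate_scene(spc)
  expect_identical(scn$annotated$image, scn2$annotated$image)
  expect_identical(lapply(scn$annotated$ground_truth, pixel_set),
                   lapply(scn2$annotated$ground_truth, pixel_set))

  # a different seed gives a different scene
  scn3 <- generate_scene(scene_spec(side = 512, n_objects = 50, seed = 22))
  expect_false(identical(scn$annotated$image, scn3$annotated$image))
})

test_that("a zero overlap cap yields pairwise-disjoint ground truth", {
  spc <- scene_spec(side = 512, n_objects = 40, max_overlap = 0, seed = 9)
  scn <- generate_scene(spc, render = FALSE)
  gts <- scn$annotated$ground_truth
  for (i in 1:(length(gts) - 1)) for (j in (i + 1):length(gts)) {
    expect_equal(iou(gts[[i]], gts[[j]]), 0)
  }
})

test_that("objects stay inside the cell ellipse and clear of the nucleus", {
  spc <- scene_spec(side = 512, n_objects = 40, seed = 33)
  scn <- generate_scene(spc, render = FALSE)
  cell_c <- rep(512 / 2, 2)
  cell_a <- spc$cell_axes_frac * 512
  nuc_a <- spc$nucleus_axes_frac * 512
  for (i in seq_len(40)) {
    p <- scn$centers[i, ]; r <- scn$radii_px[i]
    expect_lte(sum(((p - cell_c) / pmax(cell_a - r, 1))^2), 1)
    expect_gt(sum(((p - cell_c) / (nuc_a + r))^2), 1)
  }
})

test_that("every rendered object has a toroidal profile (dim center, bright ring)", {
  spc <- scene_spec(side = 1024, n_objects = 100, noise_sd = 0, seed = 17)
  scn <- generate_scene(spc)
  img <- scn$annotated$image
  for (i in seq_len(100)) {
    cen <- round(scn$centers[i, ])
    r <- scn$radii_px[i]
    center_val <- img[cen[1], cen[2]]
    ring_px <- img[cbind(round(cen[1] + 0.75 * r * cos(seq(0, 2 * pi, 0.5))),
                         round(cen[2] + 0.75 * r * sin(seq(0, 2 * pi, 0.5))))]
    expect_lt(center_val, mean(ring_px))   # central minimum
  }
})

test_that("cohort generation encodes the effect model with exact bookkeeping", {
  coh <- generate_cohort(c("day5", "day7"), n_cells_per_timepoint = 6,
                         base_spec = scene_spec(side = 512, n_objects = 40),
                         effect = list(count_multiplier = c(1, 1.5),
                                       radius_multiplier = c(1, 1)),
                         seed = 77)
  expect_length(coh$records, 12)
  expect_equal(nrow(coh$cells), 12)

  mt <- morphometrics_table(coh$records, trim = FALSE)
  # recorded counts equal the generator's bookkeeping exactly
  expect_equal(mt$cells$n_buchnera, coh$cells$n_true)
  # the count step is visible in the group means
  m5 <- mean(mt$cells$n_buchnera[mt$cells$timepoint == "day5"])
  m7 <- mean(mt$cells$n_buchnera[mt$cells$timepoint == "day7"])
  expect_gt(m7 / m5, 1.2)

  # density recovery: density x cytoplasm = count identically
  expect_equal(mt$cells$density_per_um2 * mt$cells$cytoplasm_area_um2,
               as.numeric(mt$cells$n_buchnera))

  # reproducibility
  coh2 <- generate_cohort(c("day5", "day7"), n_cells_per_timepoint = 6,
                          base_spec = scene_spec(side = 512, n_objects = 40),
                          effect = list(count_multiplier = c(1, 1.5),
                                        radius_multiplier = c(1, 1)),
                          seed = 77)
  expect_identical(coh$cells, coh2$cells)
})

test_that("rasterized and analytic cohort cells agree on the density metric", {
  base <- scene_spec(side = 512, n_objects = 25)
  coh_r <- generate_cohort(c("a", "b"), n_cells_per_timepoint = 2,
                           base_spec = base, seed = 5, rasterize = TRUE)
  coh_a <- generate_cohort(c("a", "b"), n_cells_per_timepoint = 2,
                           base_spec = base, seed = 5, rasterize = FALSE)
  mr <- morphometrics_table(coh_r$records, trim = FALSE)
  ma <- morphometrics_table(coh_a$records, trim = FALSE)
  expect_equal(mr$cells$n_buchnera, ma$cells$n_buchnera)
  expect_equal(mr$cells$density_per_um2, ma$cells$density_per_um2)
  # pixel-quantized object areas track the analytic disk areas closely
  expect_equal(mean(mr$objects$area_um2), mean(ma$objects$area_um2),
               tolerance = 0.02)
})

test_that("scene export writes image, COCO truth, and measurements", {
  dir <- file.path(tempdir(), "scene_out")
  spc <- scene_spec(side = 512, n_objects = 15, seed = 3)
  scn <- generate_scene(spc)
  paths <- write_scene(scn, dir)
  expect_true(all(file.exists(paths)))
  doc <- read_coco(paths["coco"])
  expect_length(doc$annotations, 15)
  rt <- coco_masks(doc, 1L)
  expect_equal(vapply(rt, mask_area, integer(1)),
               vapply(scn$annotated$ground_truth, mask_area, integer(1)))
  img <- read_image(paths["png"])
  expect_equal(dim(img$image), c(512L, 512L))
})
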