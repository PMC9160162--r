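# Helper: detections whose masks are the ground truth with given scores.
dets_from <- function(masks, scores) {
  lapply(seq_along(masks), function(i) new_detection(masks[[i]], scores[i]))
}

test_that("matching is one-to-one with a strict IoU bound", {
  gts <- list(rect_mask(0, 0, 10, 10), rect_mask(40, 40, 10, 10))
  preds <- dets_from(gts, c(0.9, 0.8))
  m <- match_detections(preds, gts)
  expect_equal(nrow(m$tp), 2)
  expect_length(m$fp, 0)
  expect_length(m$fn, 0)

  # two predictions over one GT: best-scoring one claims it, other is FP
  preds2 <- dets_from(list(gts[[1]], gts[[1]]), c(0.7, 0.95))
  m2 <- match_detections(preds2, list(gts[[1]]))
  expect_equal(nrow(m2$tp), 1)
  expect_equal(m2$tp$pred, 2)   # higher score matched first
  expect_equal(m2$fp, 1)

  # IoU exactly 0.5 is a false positive (strict > 0.5)
  gt <- rect_mask(0, 0, 10, 20)
  pred_half <- new_detection(rect_mask(0, 0, 10, 10), 0.9)  # IoU = 100/200
  expect_equal(iou(pred_half$mask, gt), 0.5)
  m3 <- match_detections(list(pred_half), list(gt))
  expect_equal(nrow(m3$tp), 0)
  expect_equal(m3$fp, 1)
  expect_equal(m3$fn, 1)
})

test_that("precision, recall and F1 follow their definitions", {
  gts <- lapply(1:10, function(i) rect_mask(20 * i, 0, 8, 8))
  preds <- c(dets_from(gts[1:8], seq(0.9, 0.97, 0.01)),
             list(new_detection(rect_mask(500, 500, 8, 8), 0.6),
                  new_detection(rect_mask(500, 520, 8, 8), 0.6)))
  m <- match_detections(preds, gts)
  prf <- precision_recall_f1(m, 10)
  expect_equal(as.numeric(prf), c(0.8, 0.8, 0.8))

  # harmonic mean at the reported operating point of the reference detector
  p <- 0.885; r <- 0.809
  expect_equal(round(2 * p * r / (p + r), 3), 0.845)

  none <- match_detections(list(), gts)
  prf0 <- precision_recall_f1(none, 10)
  expect_equal(as.numeric(prf0), c(1, 0, 0))
  expect_true(attr(prf0, "degenerate"))
})

test_that("equal-count binning yields 100 thresholds, or one per distinct score", {
  gts <- lapply(1:40, function(i) rect_mask(10 * i, 10 * ((i %% 20) + 1), 6, 6))
  rng <- make_rng(55)
  scores <- 0.01 + 0.99 * rng(2000)
  preds <- lapply(seq_len(2000), function(i) {
    new_detection(rect_mask(floor(rng(1) * 900), floor(rng(1) * 900), 6, 6),
                  scores[i])
  })
  curve <- pr_curve(preds, gts)
  expect_length(curve$thresholds, 100)
  expect_equal(curve$thresholds, sort(curve$thresholds))

  # fewer distinct scores than bins: one threshold per distinct score
  preds30 <- lapply(1:30, function(i) {
    new_detection(rect_mask(10 * i, 10, 6, 6), i / 31)
  })
  curve30 <- pr_curve(preds30, gts[1:5])
  expect_length(curve30$thresholds, 30)

  # retained predictions and recall are non-increasing in the threshold
  expect_true(all(diff(curve$recall) <= 0))
})

test_that("a perfect detector has precision 1 everywhere and AP 1", {
  gts <- lapply(1:20, function(i) rect_mask(24 * i, 40, 10, 10))
  preds <- dets_from(gts, seq(0.6, 0.98, length.out = 20))
  curve <- pr_curve(preds, gts)
  expect_true(all(curve$precision == 1))
  expect_equal(max(curve$recall), 1)
  expect_equal(curve$ap, 1)
})

test_that("average precision equals the trapezoid construction with (0,1) anchoring", {
  one <- list(recall = 0.5, precision = 0.5)
  expect_equal(average_precision(one), 0.375)   # (1 + 0.5)/2 * 0.5

  three <- list(recall = c(0.8, 0.5, 0.2), precision = c(0.6, 0.8, 0.95))
  expect_equal(average_precision(three),
               oracle_trapezoid_ap(three$recall, three$precision))

  # no extrapolation beyond the maximum observed recall
  capped <- list(recall = c(0.4, 0.2), precision = c(1, 1))
  expect_equal(average_precision(capped), 0.4)

  rng <- make_rng(31)
  for (k in 1:20) {
    n <- 3 + floor(rng(1) * 8)
    r <- sort(rng(n)); p <- rng(n)
    cv <- list(recall = r, precision = p)
    ap <- average_precision(cv)
    expect_equal(ap, oracle_trapezoid_ap(r, p))
    expect_gte(ap, 0); expect_lte(ap, 1)
  }
})

test_that("best threshold maximizes F1 with ties toward the smaller threshold", {
  flat <- structure(list(thresholds = c(0.1, 0.5, 0.9), f1 = c(0.7, 0.7, 0.7)),
                    class = "eq_curve")
  expect_equal(unname(best_threshold(flat)["threshold"]), 0.1)

  peak <- structure(list(thresholds = c(0.1, 0.3, 0.5, 0.7),
                         f1 = c(0.5, 0.9, 0.6, 0.2)), class = "eq_curve")
  bt <- best_threshold(peak)
  expect_equal(unname(bt["threshold"]), 0.3)
  expect_equal(unname(bt["f1"]), max(peak$f1))   # exhaustive-scan equivalence

  dec <- structure(list(thresholds = c(0.2, 0.4, 0.8), f1 = c(0.9, 0.5, 0.1)),
                   class = "eq_curve")
  expect_equal(unname(best_threshold(dec)["threshold"]), 0.2)
})

test_that("controlled degradation reproduces the count identities", {
  spc <- scene_spec(side = 512, n_objects = 40, noise_sd = 0, seed = 12)
  scn <- generate_scene(spc, render = FALSE)
  gts <- scn$annotated$ground_truth

  # dropping 20% of truth: recall = 0.8 exactly at the lowest threshold
  preds <- degrade_truth(gts, drop_frac = 0.2, image_shape = c(512, 512),
                         seed = 4)
  curve <- pr_curve(preds, gts)
  expect_equal(curve$recall[1], 0.8)
  expect_equal(curve$precision[1], 1)

  # 10 clutter objects on 40 truths: precision = 40/50 at the lowest threshold
  preds2 <- degrade_truth(gts, n_clutter = 10, image_shape = c(512, 512),
                          seed = 4)
  curve2 <- pr_curve(preds2, gts)
  expect_equal(curve2$precision[1], 0.8)
  expect_equal(curve2$recall[1], 1)

  # pristine echo: everything perfect
  preds3 <- degrade_truth(gts, image_shape = c(512, 512), seed = 4)
  prf <- precision_recall_f1(match_detections(preds3, gts), length(gts))
  expect_equal(as.numeric(prf), c(1, 1, 1))

  # clutter scores sit below truth scores, so the top of the curve is clean
  expect_true(all(utils::tail(curve2$precision, 3) == 1))
})
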