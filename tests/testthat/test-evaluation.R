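gt_row <- function(tooth, cx, w = 60, h = 100, cy = 380) {
  data.frame(tooth = tooth, x_min = cx - w / 2, y_min = cy - h / 2,
             x_max = cx + w / 2, y_max = cy + h / 2)
}

test_that("IOU matches hand geometry", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
  # symmetric, bounded
  a <- c(2, 3, 9, 12); b <- c(5, 1, 14, 10)
  expect_equal(iou(a, b), iou(b, a))
  expect_true(iou(a, b) > 0 && iou(a, b) < 1)
  expect_error(iou(c(0, 0, 0, 10), c(0, 0, 10, 10)), "positive area")
})

test_that("greedy class-aware matching counts TP/FP/FN correctly", {
  gts <- rbind(gt_row(1, 100), gt_row(2, 180), gt_row(3, 260))
  # perfect detections
  dets <- do.call(rbind, lapply(1:3, function(t) det_row(t, 100 + 80 * (t - 1), 0.9)))
  m <- match_image(dets, gts)
  expect_equal(c(m$tp, m$fp, m$fn), c(3L, 0L, 0L))
  expect_equal(m$tp, nrow(m$matched_pairs))

  # duplicate on an already-matched ground truth is a false positive
  dup <- rbind(dets, det_row(1, 102, 0.6))
  m2 <- match_image(dup, gts)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(3L, 1L, 0L))

  # detection below the IOU threshold: both FP and FN
  off <- det_row(1, 100 + 45, 0.9)  # shift 45 of width 60: IOU = 1/7
  m3 <- match_image(off, gts[1, ])
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0L, 1L, 1L))

  # wrong class never matches even with perfect overlap
  m4 <- match_image(det_row(2, 100, 0.9), gts[1, ])
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(0L, 1L, 1L))

  # counting identities on a noisy random image
  set.seed(5)
  case <- simulate_case(sim_config(p_duplicate = 0.5, spurious_rate = 4), 5)
  m5 <- match_image(case$detections, case$ground_truth)
  expect_equal(m5$tp + m5$fn, nrow(case$ground_truth))
  expect_equal(m5$tp + m5$fp, nrow(case$detections))
})

test_that("precision, recall and F1 follow their defining ratios", {
  pr <- precision_recall(list(tp = 3, fp = 1, fn = 0))
  expect_equal(unname(pr), c(0.75, 1))
  pr2 <- precision_recall(list(tp = 97, fp = 3, fn = 1))
  expect_equal(unname(pr2), c(0.97, 97 / 98))
  expect_warning(pr0 <- precision_recall(list(tp = 0, fp = 0, fn = 5)),
                 "precision undefined")
  expect_equal(unname(pr0), c(0, 0))

  expect_equal(f1_score(0.5, 0.5), 0.5)     # harmonic mean of equals
  expect_equal(f1_score(0, 0), 0)
  expect_equal(round(f1_score(0.975, 0.978), 3), 0.976)
})

test_that("average precision integrates the precision envelope", {
  expect_equal(average_precision(c(TRUE, TRUE), 2), 1)
  expect_equal(average_precision(logical(0), 3), 0)
  # ranked [TP, FP, TP] with 2 ground truths
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2), 5 / 6)
  # 11-point variant on the same ranking
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2, "11point"),
               (6 * 1 + 5 * 2 / 3) / 11)
  expect_error(average_precision(TRUE, 0), "no ground truth")
})

test_that("dataset evaluation pools images and classes correctly", {
  gt <- rbind(cbind(gt_row(1, 100), image_id = "a"),
              cbind(gt_row(2, 180), image_id = "a"),
              cbind(gt_row(1, 100), image_id = "b"))
  det <- rbind(cbind(det_row(1, 100, 0.9), image_id = "a"),
               cbind(det_row(2, 180, 0.8), image_id = "a"),
               cbind(det_row(1, 100, 0.95), image_id = "b"))
  rep <- evaluate_dataset(det, gt)
  expect_equal(rep$summary$f1, 1)
  expect_equal(rep$summary$map, 1)
  expect_equal(rep$per_class$ap[1], 1)
  expect_true(is.na(rep$per_class$ap[5]))  # no GT, no detections

  # one injected FP per image lowers precision, not recall
  fp <- rbind(det, cbind(det_row(3, 700, 0.5), image_id = "a"),
              cbind(det_row(3, 700, 0.5), image_id = "b"))
  rep2 <- suppressWarnings(evaluate_dataset(fp, gt))
  expect_lt(rep2$summary$precision, 1)
  expect_equal(rep2$summary$recall, 1)

  # orphan detections are refused by name
  orphan <- det; orphan$image_id[1] <- "zz"
  expect_error(evaluate_dataset(orphan, gt), "zz")
})

test_that("AP is invariant to monotone confidence rescaling", {
  set.seed(8)
  ds <- generate_dataset(sim_config(seed = 8), 6)
  r1 <- evaluate_dataset(ds$detections, ds$ground_truth)
  resc <- ds$detections
  resc$confidence <- resc$confidence^3       # strictly increasing on [0,1]
  r2 <- evaluate_dataset(resc, ds$ground_truth)
  expect_equal(r1$per_class$ap, r2$per_class$ap)
  expect_equal(r1$summary$map, r2$summary$map)
})

test_that("fold-wise evaluation yields per-fold rows plus an average", {
  ds <- generate_dataset(sim_config(seed = 3), 10)
  folds <- assign_folds(ds$manifest$image_ids, 5)
  rep <- evaluate_dataset(ds$detections, ds$ground_truth, folds = folds)
  expect_equal(nrow(rep$folds), 6)
  expect_equal(rep$folds$fold[6], "average")
  expect_equal(rep$folds$n_images[1:5], rep(2, 5))
  expect_equal(rep$folds$f1[6], mean(rep$folds$f1[1:5]))
  expect_equal(sum(rep$folds$n_teeth[1:5]), nrow(ds$ground_truth))
})
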