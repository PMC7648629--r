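#' Intersection over union of two axis-aligned boxes
#'
#' @param a,b Boxes as numeric vectors `c(x_min, y_min, x_max, y_max)` or
#'   single-row data frames with those columns. Both must have strictly
#'   positive area.
#' @return Overlap area divided by union area, in \[0, 1\]; 0 for
#'   disjoint boxes, 1 iff the boxes coincide.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  as_box <- function(z) {
    if (is.data.frame(z)) z <- unlist(z[1, c("x_min", "y_min", "x_max", "y_max")])
    as.numeric(z)
  }
  a <- as_box(a); b <- as_box(b)
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2]) {
    stop("boxes must have strictly positive area", call. = FALSE)
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# IOU of one det box against each row of a gt data frame (vectorized)
iou_one_vs_many <- function(det, gt) {
  iw <- pmin(det$x_max, gt$x_max) - pmax(det$x_min, gt$x_min)
  ih <- pmin(det$y_max, gt$y_max) - pmax(det$y_min, gt$y_min)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (det$x_max - det$x_min) * (det$y_max - det$y_min) +
    (gt$x_max - gt$x_min) * (gt$y_max - gt$y_min) - inter
  inter / union
}

#' Match detections of one image against its ground truth
#'
#' Class-aware greedy matching at a fixed IOU threshold: within each tooth
#' class, detections are taken in order of decreasing confidence and each
#' is matched to the still-unmatched ground-truth box of the same class
#' with the highest IOU, provided that IOU reaches the threshold. A
#' detection that matches is a true positive; one that does not (wrong
#' place, wrong class, or a duplicate on an already-claimed ground truth)
#' is a false positive; ground-truth boxes left unmatched are false
#' negatives. Duplicate detections of one tooth are therefore penalized
#' -- the error mode the pattern optimizer is designed to remove.
#'
#' @param dets Detection data frame (`tooth`, box columns, `confidence`)
#'   for one image; zero rows allowed.
#' @param gts Ground-truth data frame (`tooth`, box columns) for the same
#'   image; at most one box per tooth.
#' @param threshold IOU threshold in (0, 1\]; default 0.5.
#' @return A list of class `match_outcome`: counts `tp`, `fp`, `fn`;
#'   `matched_pairs` (data frame of detection row, ground-truth row and
#'   IOU for each match); and `outcomes`, the detections with a logical
#'   `is_tp` column, ordered by decreasing confidence, as consumed by
#'   [average_precision()].
#' @export
match_image <- function(dets, gts, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  if (is.null(dets)) dets <- empty_det()
  if (is.null(gts)) gts <- empty_det()[, GT_COLS]
  dets <- as.data.frame(dets); gts <- as.data.frame(gts)
  if (nrow(dets)) validate_detections(dets)
  if (nrow(gts)) validate_detections(gts, require_confidence = FALSE)

  ord <- order(-dets$confidence)
  dets <- dets[ord, , drop = FALSE]
  is_tp <- logical(nrow(dets))
  gt_taken <- logical(nrow(gts))
  pairs <- list()
  for (i in seq_len(nrow(dets))) {
    cand <- which(!gt_taken & gts$tooth == dets$tooth[i])
    if (!length(cand)) next
    ious <- iou_one_vs_many(dets[i, ], gts[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= threshold) {
      gt_taken[cand[j]] <- TRUE
      is_tp[i] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        data.frame(det_row = i, gt_row = cand[j], tooth = dets$tooth[i],
                   iou = ious[j])
    }
  }
  outcomes <- dets
  outcomes$is_tp <- is_tp
  matched_pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(det_row = integer(), gt_row = integer(),
               tooth = integer(), iou = numeric())
  structure(list(tp = sum(is_tp), fp = sum(!is_tp),
                 fn = sum(!gt_taken),
                 matched_pairs = matched_pairs, outcomes = outcomes),
            class = "match_outcome")
}

empty_det <- function() {
  data.frame(tooth = integer(), x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric(), confidence = numeric())
}

#' Precision and recall from match counts
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`. A 0/0
#' ratio is reported as 0 with a warning so that aggregate tables stay
#' total.
#'
#' @param m A `match_outcome` (or any list with `tp`, `fp`, `fn`).
#' @return Named numeric vector `c(precision =, recall =)`.
#' @export
precision_recall <- function(m) {
  prec <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else {
    warning("no detections: precision undefined, reported as 0", call. = FALSE)
    0
  }
  rec <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else {
    warning("no ground truth: recall undefined, reported as 0", call. = FALSE)
    0
  }
  c(precision = prec, recall = rec)
}

#' F1 score
#'
#' Harmonic mean of precision and recall; 0 when both are 0.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return The F1 score.
#' @examples
#' f1_score(0.975, 0.978)  # 0.976 to 3 decimals
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Average precision of a ranked detection list
#'
#' Area under the precision--recall curve obtained by sweeping the
#' confidence ranking of one class's detections. `method = "all"`
#' integrates the exact precision envelope over recall (all-point
#' interpolation); `method = "11point"` averages the interpolated
#' precision at recalls 0, 0.1, ..., 1.
#'
#' @param is_tp Logical vector: for each detection, in decreasing order
#'   of confidence, whether it was matched as a true positive.
#' @param n_gt Number of ground-truth boxes of the class. Must be > 0;
#'   AP is undefined for a class with no ground truth.
#' @param method `"all"` (default) or `"11point"`.
#' @return The average precision in \[0, 1\]; 0 when there are no
#'   detections.
#' @export
average_precision <- function(is_tp, n_gt, method = c("all", "11point")) {
  method <- match.arg(method)
  if (n_gt <= 0) stop("AP undefined for a class with no ground truth", call. = FALSE)
  if (!length(is_tp)) return(0)
  tp_cum <- cumsum(is_tp)
  precision <- tp_cum / seq_along(is_tp)
  recall <- tp_cum / n_gt
  # precision envelope: best precision achievable at recall >= r
  env <- rev(cummax(rev(precision)))
  if (method == "11point") {
    pts <- vapply(seq(0, 1, by = 0.1), function(r) {
      i <- which(recall >= r - 1e-12)
      if (length(i)) max(precision[i]) else 0
    }, numeric(1))
    return(mean(pts))
  }
  dr <- diff(c(0, recall))
  sum(env * dr)
}

#' Evaluate a detection set against ground truth
#'
#' Runs class-aware IOU matching image by image and aggregates: pooled
#' (micro-averaged) precision, recall and F1 over all teeth and images;
#' per-tooth-class average precision; and mAP, the macro average of the
#' per-class APs over classes with at least one ground-truth box. Works
#' on raw detector output and on optimizer output alike -- convert an
#' optimized pattern to detections with [pattern_detections()] first.
#' Classes that have detections but no ground truth anywhere get an
#' undefined AP (`NA`) and are excluded from mAP with a warning.
#'
#' When `folds` is supplied, per-fold summaries (and their average) are
#' computed alongside the pooled report, mirroring K-fold cross-validation
#' reporting.
#'
#' @param detections Data frame with `image_id`, `tooth`, box columns and
#'   `confidence`.
#' @param ground_truth Data frame with `image_id`, `tooth` and box
#'   columns; one box per (image, tooth). Its image ids define the
#'   dataset; detections for unknown images raise an error.
#' @param threshold IOU threshold, default 0.5.
#' @param ap_method Passed to [average_precision()].
#' @param folds Optional: named vector or data frame (`image_id`, `fold`)
#'   assigning each ground-truth image to a fold.
#' @return An object of class `eval_report`: list with `summary` (one-row
#'   data frame: tp, fp, fn, precision, recall, f1, map), `per_class`
#'   (per tooth: n_gt, n_det, tp, ap) and, if folds were given, `folds`
#'   (per-fold precision/recall/f1 rows plus an average row).
#' @export
evaluate_dataset <- function(detections, ground_truth, threshold = 0.5,
                             ap_method = c("all", "11point"), folds = NULL) {
  ap_method <- match.arg(ap_method)
  detections <- as.data.frame(detections)
  ground_truth <- as.data.frame(ground_truth)
  if (!"image_id" %in% names(detections) || !"image_id" %in% names(ground_truth)) {
    stop("both tables need an `image_id` column", call. = FALSE)
  }
  dup <- duplicated(ground_truth[, c("image_id", "tooth")])
  if (any(dup)) {
    stop("duplicate ground-truth (image, tooth) pairs: ",
         paste(utils::head(paste(ground_truth$image_id[dup],
                                 ground_truth$tooth[dup], sep = ":"), 5),
               collapse = ", "), call. = FALSE)
  }
  images <- unique(ground_truth$image_id)
  orphans <- setdiff(unique(detections$image_id), images)
  if (length(orphans)) {
    stop("detections reference image id(s) absent from the ground truth: ",
         paste(utils::head(orphans, 10), collapse = ", "), call. = FALSE)
  }

  per_image <- lapply(images, function(id) {
    match_image(detections[detections$image_id == id, , drop = FALSE],
                ground_truth[ground_truth$image_id == id, , drop = FALSE],
                threshold)
  })
  names(per_image) <- as.character(images)

  pool <- do.call(rbind, lapply(seq_along(per_image), function(i) {
    o <- per_image[[i]]$outcomes
    if (nrow(o)) o$image_id <- images[i]
    o
  }))
  tp <- sum(vapply(per_image, `[[`, 0L, "tp"))
  fp <- sum(vapply(per_image, `[[`, 0L, "fp"))
  fn <- sum(vapply(per_image, `[[`, 0L, "fn"))

  n_gt_class <- vapply(1:32, function(x) sum(ground_truth$tooth == x), 0L)
  per_class <- data.frame(tooth = 1:32, n_gt = n_gt_class, n_det = 0L,
                          tp = 0L, ap = NA_real_)
  for (x in 1:32) {
    rows <- if (!is.null(pool) && nrow(pool)) pool[pool$tooth == x, , drop = FALSE]
            else empty_det()
    per_class$n_det[x] <- nrow(rows)
    per_class$tp[x] <- if (nrow(rows)) sum(rows$is_tp) else 0L
    if (n_gt_class[x] > 0) {
      is_tp <- rows$is_tp[order(-rows$confidence)]
      per_class$ap[x] <- average_precision(is_tp, n_gt_class[x], ap_method)
    }
  }
  undefined <- which(is.na(per_class$ap) & per_class$n_det > 0)
  if (length(undefined)) {
    warning("AP undefined (no ground truth) for tooth class(es): ",
            paste(undefined, collapse = ", "), "; excluded from mAP",
            call. = FALSE)
  }
  map <- mean(per_class$ap[per_class$n_gt > 0])

  pr <- precision_recall(list(tp = tp, fp = fp, fn = fn))
  summary <- data.frame(tp = tp, fp = fp, fn = fn,
                        precision = pr[["precision"]],
                        recall = pr[["recall"]],
                        f1 = f1_score(pr[["precision"]], pr[["recall"]]),
                        map = map)

  fold_tab <- NULL
  if (!is.null(folds)) {
    if (is.data.frame(folds)) {
      fold_of <- stats::setNames(folds$fold, folds$image_id)
    } else {
      fold_of <- folds
    }
    unassigned <- setdiff(as.character(images), names(fold_of))
    if (length(unassigned)) {
      stop("images missing a fold assignment: ",
           paste(utils::head(unassigned, 10), collapse = ", "), call. = FALSE)
    }
    fids <- sort(unique(fold_of[as.character(images)]))
    rows <- lapply(fids, function(f) {
      imgs <- as.character(images)[fold_of[as.character(images)] == f]
      tpf <- sum(vapply(per_image[imgs], `[[`, 0L, "tp"))
      fpf <- sum(vapply(per_image[imgs], `[[`, 0L, "fp"))
      fnf <- sum(vapply(per_image[imgs], `[[`, 0L, "fn"))
      prf <- precision_recall(list(tp = tpf, fp = fpf, fn = fnf))
      data.frame(fold = as.character(f), n_images = length(imgs),
                 n_teeth = tpf + fnf,
                 precision = prf[["precision"]], recall = prf[["recall"]],
                 f1 = f1_score(prf[["precision"]], prf[["recall"]]))
    })
    fold_tab <- do.call(rbind, rows)
    avg <- data.frame(fold = "average", n_images = sum(fold_tab$n_images),
                      n_teeth = sum(fold_tab$n_teeth),
                      precision = mean(fold_tab$precision),
                      recall = mean(fold_tab$recall),
                      f1 = mean(fold_tab$f1))
    fold_tab <- rbind(fold_tab, avg)
  }

  structure(list(summary = summary, per_class = per_class,
                 folds = fold_tab, threshold = threshold,
                 ap_method = ap_method),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<eval_report> IOU >= %.2f | TP %d FP %d FN %d | P %.4f R %.4f F1 %.4f | mAP %.4f\n",
    x$threshold, s$tp, s$fp, s$fn, s$precision, s$recall, s$f1, s$map))
  if (!is.null(x$folds)) {
    cat("  folds:\n")
    print(x$folds, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
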