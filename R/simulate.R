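#' Configuration of the synthetic detector simulator
#'
#' The simulator emulates the output of a CNN tooth detector on a
#' panoramic radiograph so that the candidate optimizer and the
#' evaluation metrics can be exercised without images. It lays out two
#' straight 16-tooth rows (upper jaw right-to-left as positions 1--16,
#' lower jaw left-to-right as 17--32), drops teeth at random to emulate
#' edentulous positions, and then corrupts the per-tooth detections with
#' the detector's characteristic failure modes: missed detections,
#' displaced double detections of one tooth, neighbor label swaps, and
#' spurious boxes, with confidence distributions that overlap between
#' correct and erroneous candidates so that confidence alone cannot
#' separate them.
#'
#' Adjacent center spacing is drawn from a normal distribution and
#' clipped to the plateau of the adjacent-neighbor coordinate score, so
#' a noise-free arch scores a positional relationship of (nearly) 1 and
#' the optimizer's preference for true candidates is analyzable.
#'
#' @param image_width,image_height Image size in pixels (default
#'   2000 x 1000, typical of panoramic radiographs).
#' @param adjacent_spacing_mean,adjacent_spacing_sd Mean and sd (pixels)
#'   of the horizontal center distance between adjacent teeth; defaults
#'   80 and 8, centered in the adjacent-score plateau.
#' @param spacing_clip Interval the spacing draws are clipped to;
#'   defaults to the plateau `c(47, 114)` of the default adjacent
#'   thresholds.
#' @param tooth_width,tooth_height Uniform ranges (pixels) for box sizes.
#' @param p_missing Per-tooth probability the tooth is absent from the
#'   mouth (ground truth), default 0.08.
#' @param p_missdetect Probability the detector misses a present tooth,
#'   default 0.02.
#' @param p_duplicate Probability a present tooth additionally gets a
#'   displaced duplicate detection, default 0.2.
#' @param p_label_swap Probability a correct detection carries an
#'   adjacent tooth's label, default 0.03.
#' @param spurious_rate Expected number (Poisson mean) of spurious boxes
#'   per image, default 2.
#' @param conf_true,conf_false Uniform ranges of confidence scores for
#'   correct and erroneous candidates; defaults `c(0.7, 1)` and
#'   `c(0.3, 0.8)` (overlapping by design).
#' @param seed Base RNG seed; case `i` of a dataset uses `seed + i`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(image_width = 2000, image_height = 1000,
                       adjacent_spacing_mean = 80, adjacent_spacing_sd = 8,
                       spacing_clip = c(47, 114),
                       tooth_width = c(55, 75), tooth_height = c(90, 140),
                       p_missing = 0.08, p_missdetect = 0.02,
                       p_duplicate = 0.2, p_label_swap = 0.03,
                       spurious_rate = 2,
                       conf_true = c(0.7, 1.0), conf_false = c(0.3, 0.8),
                       seed = 1L) {
  probs <- c(p_missing = p_missing, p_missdetect = p_missdetect,
             p_duplicate = p_duplicate, p_label_swap = p_label_swap)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  if (adjacent_spacing_mean <= 0 || adjacent_spacing_sd < 0 ||
      spurious_rate < 0) {
    stop("spacing parameters and spurious_rate must be non-negative",
         call. = FALSE)
  }
  stopifnot(length(spacing_clip) == 2, spacing_clip[1] < spacing_clip[2],
            length(conf_true) == 2, length(conf_false) == 2)
  structure(list(image_width = image_width, image_height = image_height,
                 adjacent_spacing_mean = adjacent_spacing_mean,
                 adjacent_spacing_sd = adjacent_spacing_sd,
                 spacing_clip = spacing_clip,
                 tooth_width = tooth_width, tooth_height = tooth_height,
                 p_missing = p_missing, p_missdetect = p_missdetect,
                 p_duplicate = p_duplicate, p_label_swap = p_label_swap,
                 spurious_rate = spurious_rate,
                 conf_true = conf_true, conf_false = conf_false,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a ground-truth dental arch
#'
#' Draws one synthetic mouth: per-tooth presence (independent
#' `p_missing`), horizontal centers from clipped normal adjacent
#' spacings along two straight rows, and a box per present tooth. UTN
#' order is respected: position 1 sits at the patient's upper right
#' (image left/right is irrelevant to the score, which only uses center
#' distances), 16 at the upper left, and 17 starts below 16 so that
#' cross-jaw neighbors are horizontally close. Uses the current RNG
#' state; seed it (or use [simulate_case()]) for reproducibility.
#'
#' @param config A [sim_config()].
#' @return Ground-truth data frame (`tooth`, `x_min`, `y_min`, `x_max`,
#'   `y_max`), one row per present tooth.
#' @export
generate_arch <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  present <- stats::runif(32) >= config$p_missing

  row_centers <- function() {
    gaps <- stats::rnorm(15, config$adjacent_spacing_mean,
                         config$adjacent_spacing_sd)
    gaps <- pmin(pmax(gaps, config$spacing_clip[1]), config$spacing_clip[2])
    x <- c(0, cumsum(gaps))
    # center the row span in the image
    x + (config$image_width - x[16]) / 2
  }
  # upper row: tooth 1 rightmost -> reverse; lower row: tooth 17 leftmost
  upper_x <- rev(row_centers())
  lower_x <- row_centers()
  cx <- c(upper_x, lower_x)
  cy <- c(rep(0.38 * config$image_height, 16),
          rep(0.62 * config$image_height, 16)) + stats::rnorm(32, 0, 5)

  w <- stats::runif(32, config$tooth_width[1], config$tooth_width[2])
  h <- stats::runif(32, config$tooth_height[1], config$tooth_height[2])
  gt <- data.frame(tooth = 1:32,
                   x_min = cx - w / 2, y_min = cy - h / 2,
                   x_max = cx + w / 2, y_max = cy + h / 2)
  gt <- gt[present, , drop = FALSE]
  rownames(gt) <- NULL
  gt
}

#' Corrupt a ground-truth arch into detector-style candidates
#'
#' Applies the simulator's noise model to a ground-truth arch:
#' each present tooth is detected with probability `1 - p_missdetect` as
#' a jittered copy of its box (translation bounded so the IOU against
#' the ground truth always stays >= 0.5) with confidence from
#' `conf_true`, optionally relabeled to an adjacent position
#' (`p_label_swap`); with probability `p_duplicate` a horizontally
#' displaced duplicate (IOU < 0.5 by construction) with confidence from
#' `conf_false` is added; and `Poisson(spurious_rate)` spurious boxes
#' with random labels and positions are appended. Uses the current RNG
#' state.
#'
#' @param gt Ground-truth data frame from [generate_arch()].
#' @param config A [sim_config()].
#' @return Detection data frame (`tooth`, box columns, `confidence`).
#' @export
corrupt_detections <- function(gt, config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list()
  runif2 <- function(range) stats::runif(1, range[1], range[2])
  for (i in seq_len(nrow(gt))) {
    tooth <- gt$tooth[i]
    w <- gt$x_max[i] - gt$x_min[i]
    h <- gt$y_max[i] - gt$y_min[i]
    if (stats::runif(1) >= config$p_missdetect) {
      # |shift| <= 0.12 of each dimension keeps IOU >= 0.72 > 0.5
      dx <- stats::runif(1, -0.12, 0.12) * w
      dy <- stats::runif(1, -0.12, 0.12) * h
      label <- tooth
      if (stats::runif(1) < config$p_label_swap) {
        opts <- intersect(tooth + c(-1L, 1L), 1:32)
        label <- opts[sample.int(length(opts), 1)]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tooth = label,
        x_min = gt$x_min[i] + dx, y_min = gt$y_min[i] + dy,
        x_max = gt$x_max[i] + dx, y_max = gt$y_max[i] + dy,
        confidence = runif2(config$conf_true))
    }
    if (stats::runif(1) < config$p_duplicate) {
      # displace 0.4..0.8 widths sideways: IOU <= 0.43 < 0.5, a real FP
      dx <- sample(c(-1, 1), 1) * stats::runif(1, 0.4, 0.8) * w
      dy <- stats::runif(1, -0.1, 0.1) * h
      rows[[length(rows) + 1L]] <- data.frame(
        tooth = tooth,
        x_min = gt$x_min[i] + dx, y_min = gt$y_min[i] + dy,
        x_max = gt$x_max[i] + dx, y_max = gt$y_max[i] + dy,
        confidence = runif2(config$conf_false))
    }
  }
  n_spur <- stats::rpois(1, config$spurious_rate)
  for (s in seq_len(n_spur)) {
    w <- runif2(config$tooth_width)
    h <- runif2(config$tooth_height)
    cx <- stats::runif(1, w / 2, config$image_width - w / 2)
    cy <- stats::runif(1, h / 2, config$image_height - h / 2)
    rows[[length(rows) + 1L]] <- data.frame(
      tooth = sample.int(32, 1),
      x_min = cx - w / 2, y_min = cy - h / 2,
      x_max = cx + w / 2, y_max = cy + h / 2,
      confidence = runif2(config$conf_false))
  }
  if (!length(rows)) return(empty_det())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate one image (ground truth + noisy detections)
#'
#' Seeds the RNG with `seed`, draws an arch and corrupts it. Identical
#' seeds give bit-identical cases.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this case.
#' @param image_id Identifier for the case.
#' @return List of class `synthetic_case` with `image_id`, `seed`,
#'   `ground_truth` and `detections`.
#' @export
simulate_case <- function(config, seed, image_id = paste0("img", seed)) {
  set.seed(as.integer(seed))
  gt <- generate_arch(config)
  det <- corrupt_detections(gt, config)
  structure(list(image_id = image_id, seed = as.integer(seed),
                 ground_truth = gt, detections = det),
            class = "synthetic_case")
}

#' Generate a seeded synthetic detection dataset
#'
#' Simulates `n_images` cases with per-case seeds `seed + 1 .. seed + n`,
#' and returns pooled ground-truth and detection tables (keyed by
#' `image_id`) plus a manifest recording the configuration and every
#' per-image seed, from which the dataset can be regenerated
#' bit-identically.
#'
#' @param config A [sim_config()]; its `seed` is the base seed.
#' @param n_images Number of images, default 100.
#' @return List of class `synthetic_dataset` with `ground_truth`,
#'   `detections` (both with `image_id`), and `manifest` (list with
#'   `config`, `n_images`, `seeds`, `image_ids`).
#' @export
generate_dataset <- function(config = sim_config(), n_images = 100) {
  stopifnot(n_images >= 1)
  seeds <- config$seed + seq_len(n_images)
  ids <- sprintf("img%05d", seq_len(n_images))
  gt_all <- list(); det_all <- list()
  for (i in seq_len(n_images)) {
    case <- simulate_case(config, seeds[i], ids[i])
    if (nrow(case$ground_truth)) {
      case$ground_truth$image_id <- ids[i]
      gt_all[[i]] <- case$ground_truth
    }
    if (nrow(case$detections)) {
      case$detections$image_id <- ids[i]
      det_all[[i]] <- case$detections
    }
  }
  structure(list(
    ground_truth = do.call(rbind, gt_all),
    detections = do.call(rbind, det_all),
    manifest = list(config = unclass(config), n_images = n_images,
                    seeds = seeds, image_ids = ids)),
    class = "synthetic_dataset")
}

#' Regenerate a dataset from its manifest
#'
#' @param manifest The `manifest` element of a [generate_dataset()]
#'   result (possibly read back from disk).
#' @return The regenerated `synthetic_dataset`, bit-identical to the
#'   original.
#' @export
dataset_from_manifest <- function(manifest) {
  config <- do.call(sim_config, manifest$config)
  generate_dataset(config, manifest$n_images)
}

#' Assign images to contiguous cross-validation folds
#'
#' @param image_ids Character vector of image ids.
#' @param n_folds Number of folds; must divide or nearly divide the
#'   number of images (blocks differ by at most one).
#' @return Named integer vector mapping image id to fold 1..n_folds.
#' @export
assign_folds <- function(image_ids, n_folds = 10) {
  n <- length(image_ids)
  stopifnot(n_folds >= 1, n_folds <= n)
  fold <- rep(seq_len(n_folds), each = ceiling(n / n_folds))[seq_len(n)]
  stats::setNames(fold, image_ids)
}
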