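#' Read and write detection tables
#'
#' Detections travel in either of two plain-text formats:
#' \describe{
#'   \item{CSV}{columns `image_id, tooth, x_min, y_min, x_max, y_max,
#'     confidence` (corner coordinates).}
#'   \item{COCO-style results JSON}{an array of records
#'     `{image_id, category_id, bbox, score}` with `bbox = [x, y, width,
#'     height]` (the COCO convention); `category_id` is the UTN tooth
#'     number. Real detector output in COCO form can be dropped in
#'     unchanged.}
#' }
#' Boxes are converted to corner form internally. Validation rejects
#' unknown tooth categories, malformed boxes and confidences outside
#' \[0, 1\], naming the offending records.
#'
#' @param path File path.
#' @param format `"csv"` or `"coco"`; guessed from the file extension
#'   when omitted (`.json` means COCO).
#' @return `read_detections()` returns the detection data frame (with
#'   `image_id`); writers return `path` invisibly.
#' @export
read_detections <- function(path, format = c("auto", "csv", "coco")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "coco") {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(recs) == 0 || NROW(recs) == 0) {
      warning("empty detections file: ", path, call. = FALSE)
      df <- empty_det(); df$image_id <- character()
      return(df[, c("image_id", DET_COLS)])
    }
    needed <- c("image_id", "category_id", "bbox", "score")
    if (!all(needed %in% names(recs))) {
      stop("COCO results file must have fields ",
           paste(needed, collapse = ", "), call. = FALSE)
    }
    bb <- do.call(rbind, recs$bbox)
    df <- data.frame(image_id = as.character(recs$image_id),
                     tooth = recs$category_id,
                     x_min = bb[, 1], y_min = bb[, 2],
                     x_max = bb[, 1] + bb[, 3], y_max = bb[, 2] + bb[, 4],
                     confidence = recs$score)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(df)) {
      warning("empty detections file: ", path, call. = FALSE)
      df <- empty_det(); df$image_id <- character()
      return(df[, c("image_id", DET_COLS)])
    }
    df$image_id <- as.character(df$image_id)
  }
  validate_detections(df)
  df$tooth <- as.integer(df$tooth)
  df[, c("image_id", DET_COLS)]
}

#' @rdname read_detections
#' @param detections Detection data frame with `image_id`.
#' @export
write_detections <- function(detections, path,
                             format = c("auto", "csv", "coco")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "coco") {
    recs <- lapply(seq_len(nrow(detections)), function(i) {
      d <- detections[i, ]
      list(image_id = d$image_id, category_id = d$tooth,
           bbox = c(d$x_min, d$y_min, d$x_max - d$x_min, d$y_max - d$y_min),
           score = d$confidence)
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(detections[, c("image_id", DET_COLS)], path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read and write ground-truth tables
#'
#' Same formats as [read_detections()] but without confidences: CSV
#' columns `image_id, tooth, x_min, y_min, x_max, y_max`, or a COCO
#' annotation file whose `annotations` array holds
#' `{image_id, category_id, bbox}`. A tooth missing from an image simply
#' has no row; duplicate (image, tooth) rows are rejected.
#'
#' @inheritParams read_detections
#' @return The ground-truth data frame.
#' @export
read_ground_truth <- function(path, format = c("auto", "csv", "coco")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "coco") {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    recs <- if (!is.null(obj$annotations)) obj$annotations else obj
    if (length(recs) == 0 || NROW(recs) == 0) {
      warning("empty ground-truth file: ", path, call. = FALSE)
      df <- empty_det()[, GT_COLS]; df$image_id <- character()
      return(df[, c("image_id", GT_COLS)])
    }
    bb <- do.call(rbind, recs$bbox)
    df <- data.frame(image_id = as.character(recs$image_id),
                     tooth = recs$category_id,
                     x_min = bb[, 1], y_min = bb[, 2],
                     x_max = bb[, 1] + bb[, 3], y_max = bb[, 2] + bb[, 4])
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(df)) {
      warning("empty ground-truth file: ", path, call. = FALSE)
      df <- empty_det()[, GT_COLS]; df$image_id <- character()
      return(df[, c("image_id", GT_COLS)])
    }
    df$image_id <- as.character(df$image_id)
  }
  validate_detections(df, require_confidence = FALSE)
  dup <- duplicated(df[, c("image_id", "tooth")])
  if (any(dup)) {
    stop("duplicate (image, tooth) ground-truth rows: ",
         paste(utils::head(paste(df$image_id[dup], df$tooth[dup], sep = ":"), 5),
               collapse = ", "), call. = FALSE)
  }
  df$tooth <- as.integer(df$tooth)
  df[, c("image_id", GT_COLS)]
}

#' @rdname read_ground_truth
#' @param ground_truth Ground-truth data frame with `image_id`.
#' @export
write_ground_truth <- function(ground_truth, path,
                               format = c("auto", "csv", "coco")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "coco") {
    ann <- lapply(seq_len(nrow(ground_truth)), function(i) {
      g <- ground_truth[i, ]
      list(id = i, image_id = g$image_id, category_id = g$tooth,
           bbox = c(g$x_min, g$y_min, g$x_max - g$x_min, g$y_max - g$y_min))
    })
    obj <- list(
      images = lapply(unique(ground_truth$image_id),
                      function(id) list(id = id)),
      annotations = ann,
      categories = lapply(1:32, function(x)
        list(id = x, name = paste0("T", x),
             fdi = utn_to_fdi(x))))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(ground_truth[, c("image_id", GT_COLS)], path,
                     row.names = FALSE)
  }
  invisible(path)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.json$", path, ignore.case = TRUE)) "coco" else "csv"
}

#' Run configuration
#'
#' Bundles every tunable of a pipeline run -- score thresholds and
#' weights, the missing-candidate confidence surrogate, sweep mode, IOU
#' threshold, AP interpolation style and seed -- so that a run's exact
#' settings can be serialized next to its outputs and replayed. Settings
#' are read from / written to YAML.
#'
#' @param weights A [score_weights()].
#' @param params A [delta_params()].
#' @param missing_conf Confidence surrogate for the missing candidate.
#' @param sweep_mode `"immediate"` or `"batch"`.
#' @param restrict_omega_to_jaw Truncate neighborhoods at the jaw
#'   boundary.
#' @param iou_threshold IOU threshold for evaluation.
#' @param ap_method `"all"` or `"11point"`.
#' @param seed Base RNG seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(weights = score_weights(), params = delta_params(),
                       missing_conf = params$k,
                       sweep_mode = "immediate",
                       restrict_omega_to_jaw = FALSE,
                       iou_threshold = 0.5, ap_method = "all",
                       seed = 1L) {
  structure(list(weights = weights, params = params,
                 missing_conf = missing_conf, sweep_mode = sweep_mode,
                 restrict_omega_to_jaw = restrict_omega_to_jaw,
                 iou_threshold = iou_threshold, ap_method = ap_method,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- list(
    omega_c = config$weights$omega_c, omega_p = config$weights$omega_p,
    delta_near = config$params$near, delta_far = config$params$far,
    k = config$params$k, missing_conf = config$missing_conf,
    sweep_mode = config$sweep_mode,
    restrict_omega_to_jaw = config$restrict_omega_to_jaw,
    iou_threshold = config$iou_threshold, ap_method = config$ap_method,
    seed = config$seed)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname run_config
#' @param config For `write_config`, a `run_config` object.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    weights = score_weights(y$omega_c, y$omega_p),
    params = delta_params(near = y$delta_near, far = y$delta_far, k = y$k),
    missing_conf = y$missing_conf,
    sweep_mode = y$sweep_mode,
    restrict_omega_to_jaw = isTRUE(y$restrict_omega_to_jaw),
    iou_threshold = y$iou_threshold, ap_method = y$ap_method,
    seed = y$seed)
}

#' Write an evaluation report to CSV and JSON
#'
#' Writes `summary.csv` (pooled precision/recall/F1/mAP), `per_class.csv`
#' (per-tooth AP table), `folds.csv` when fold results are present, and
#' `report.json` with all three.
#'
#' @param report An `eval_report` from [evaluate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_class, file.path(dir, "per_class.csv"),
                   row.names = FALSE)
  if (!is.null(report$folds)) {
    utils::write.csv(report$folds, file.path(dir, "folds.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(summary = report$summary, per_class = report$per_class,
         folds = report$folds, threshold = report$threshold,
         ap_method = report$ap_method),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
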