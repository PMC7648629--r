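#' @keywords internal
"_PACKAGE"

DET_COLS <- c("tooth", "x_min", "y_min", "x_max", "y_max", "confidence")
GT_COLS  <- c("tooth", "x_min", "y_min", "x_max", "y_max")

#' Validate a detection or ground-truth table
#'
#' Checks tooth labels (integers 1--32), box geometry (`x_min < x_max`,
#' `y_min < y_max`, strictly positive area) and, for detections, confidence
#' scores in \[0, 1\]. Errors name the offending rows so malformed detector
#' output can be located.
#'
#' @param df A data frame with columns `tooth`, `x_min`, `y_min`, `x_max`,
#'   `y_max` and, when `require_confidence = TRUE`, `confidence`.
#' @param require_confidence Whether a `confidence` column is mandatory.
#' @return `df`, invisibly, with `tooth` coerced to integer.
#' @export
validate_detections <- function(df, require_confidence = TRUE) {
  needed <- if (require_confidence) DET_COLS else GT_COLS
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_tooth <- which(is.na(df$tooth) | df$tooth < 1 | df$tooth > 32 |
                     df$tooth != as.integer(df$tooth))
  if (length(bad_tooth)) {
    stop("invalid tooth label (must be integer 1..32) in row(s): ",
         paste(utils::head(bad_tooth, 10), collapse = ", "), call. = FALSE)
  }
  bad_box <- which(!(df$x_min < df$x_max & df$y_min < df$y_max))
  if (length(bad_box)) {
    stop("degenerate bounding box (requires x_min < x_max, y_min < y_max) in row(s): ",
         paste(utils::head(bad_box, 10), collapse = ", "), call. = FALSE)
  }
  if (require_confidence) {
    bad_conf <- which(is.na(df$confidence) | df$confidence < 0 | df$confidence > 1)
    if (length(bad_conf)) {
      stop("confidence outside [0, 1] in row(s): ",
           paste(utils::head(bad_conf, 10), collapse = ", "), call. = FALSE)
    }
  }
  df$tooth <- as.integer(df$tooth)
  invisible(df)
}

#' Horizontal box center
#'
#' @param df Data frame with `x_min` and `x_max` columns.
#' @return Numeric vector of horizontal center coordinates, the quantity
#'   the positional relationship score compares between neighbors.
#' @export
box_center_x <- function(df) (df$x_min + df$x_max) / 2

#' Index raw detections into a per-tooth candidate set
#'
#' Groups one image's detections by tooth position 1--32 and ranks the
#' candidates of each tooth by strictly non-increasing confidence
#' (rank 1 = most confident; ties keep input order, so indexing is
#' deterministic). Every tooth additionally carries the implicit rank-0
#' "missing tooth" candidate, which has no box and no confidence; teeth
#' with no detections have only that option. The resulting object is the
#' search space of the pattern optimizer: the optimizer picks, for each
#' tooth, one rank in `0..N(x)`.
#'
#' @param detections Data frame of raw detections for one image with
#'   columns `tooth`, `x_min`, `y_min`, `x_max`, `y_max`, `confidence`.
#'   May have zero rows.
#' @param image_id Identifier carried along in the result.
#' @return An object of class `candidate_set`: a list with elements
#'   `image_id`; `detections`, the validated input sorted by
#'   `(tooth, rank)` with a `rank` column added (rank-0 missing candidates
#'   are implicit, not rows); `n`, integer vector of length 32 giving
#'   `N(x)`, the number of real candidates per tooth; and per-tooth lists
#'   `centers` and `confidences` used by the scoring engine.
#' @examples
#' det <- data.frame(tooth = c(1, 1), x_min = c(100, 140), y_min = 0,
#'                   x_max = c(160, 200), y_max = 100,
#'                   confidence = c(0.7, 0.95))
#' cs <- candidate_set(det)
#' cs$detections$confidence  # 0.95 first: ranked by confidence
#' @export
candidate_set <- function(detections = NULL, image_id = "image") {
  if (is.null(detections) || nrow(as.data.frame(detections)) == 0L) {
    detections <- data.frame(tooth = integer(), x_min = numeric(),
                             y_min = numeric(), x_max = numeric(),
                             y_max = numeric(), confidence = numeric())
  }
  detections <- as.data.frame(detections)[, DET_COLS, drop = FALSE]
  validate_detections(detections)
  # stable sort: tooth ascending, confidence descending, input order on ties
  ord <- order(detections$tooth, -detections$confidence)
  detections <- detections[ord, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(detections)), detections$tooth,
                     FUN = seq_along)
  detections$rank <- as.integer(rank)
  rownames(detections) <- NULL

  n <- integer(32)
  centers <- vector("list", 32)
  confidences <- vector("list", 32)
  cx <- box_center_x(detections)
  for (x in 1:32) {
    idx <- which(detections$tooth == x)
    n[x] <- length(idx)
    centers[[x]] <- cx[idx]
    confidences[[x]] <- detections$confidence[idx]
  }
  structure(
    list(image_id = image_id, detections = detections, n = n,
         centers = centers, confidences = confidences),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set>", x$image_id, "\n")
  cat("  teeth with candidates:", sum(x$n > 0), "of 32;",
      "total candidates:", sum(x$n), "\n")
  invisible(x)
}

#' Materialize a pattern's selected detections
#'
#' A pattern assigns one candidate rank (0 = missing) to each of the 32
#' tooth positions. This returns the selected non-missing candidates as a
#' detection table, i.e. the refined detector output after optimization.
#'
#' @param cs A [candidate_set()].
#' @param ranks Integer vector of length 32; entry `x` in `0..N(x)`.
#' @return Data frame with the columns of `cs$detections` for the chosen
#'   rank >= 1 candidates.
#' @export
pattern_detections <- function(cs, ranks) {
  check_ranks(cs, ranks)
  keep <- cs$detections$rank == ranks[cs$detections$tooth]
  out <- cs$detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_ranks <- function(cs, ranks) {
  stopifnot(inherits(cs, "candidate_set"))
  if (length(ranks) != 32L || anyNA(ranks) ||
      any(ranks < 0L) || any(ranks > cs$n)) {
    stop("`ranks` must have one entry per tooth 1..32, each in 0..N(x)",
         call. = FALSE)
  }
  invisible(as.integer(ranks))
}

# Selected horizontal centers / confidences for a rank vector (NA / missing
# placeholder where rank 0 is chosen).  Workhorse state for the scorer.
pattern_state <- function(cs, ranks, missing_conf) {
  ranks <- check_ranks(cs, ranks)
  centers <- rep(NA_real_, 32)
  conf <- rep(missing_conf, 32)
  sel <- which(ranks > 0L)
  for (x in sel) {
    centers[x] <- cs$centers[[x]][ranks[x]]
    conf[x] <- cs$confidences[[x]][ranks[x]]
  }
  list(centers = centers, conf = conf)
}
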