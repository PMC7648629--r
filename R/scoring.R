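#' Parameters of the coordinate score delta
#'
#' The coordinate score is a trapezoid-shaped membership function of the
#' horizontal distance between the box centers of two teeth. It is 0 when
#' the distance is implausibly small (below `a`) or large (above `d`),
#' 1 on the plausible plateau `[b, c]`, ramps linearly between `k` and 1
#' on `(a, b)` and `(c, d)`, and takes the neutral value `k` whenever
#' either tooth is missing. First-order (adjacent) and second-order
#' (next-but-one) neighbors use different threshold tuples because the
#' expected center distance roughly doubles. Thresholds are in pixels of
#' the source radiograph; `scale` rescales all eight thresholds at once
#' for images resized by a known factor.
#'
#' At the threshold points themselves the trapezoid is closed: the ramps
#' attain `k` at `a` and `d` and 1 at `b` and `c`, so the only
#' discontinuities are the jumps 0 to `k` at `a` and `d`.
#'
#' @param near Numeric `(a, b, c, d)` for first-order neighbors. Default
#'   `c(30, 47, 114, 130)`.
#' @param far Numeric `(a, b, c, d)` for second-order neighbors. Default
#'   `c(80, 97, 164, 180)`.
#' @param k Score assigned when a neighbor (or the tooth itself) is
#'   missing, and the ramp endpoint value; in \[0, 1\], default 0.35.
#' @param scale Global multiplier applied to all thresholds; default 1.
#' @return An object of class `delta_params`.
#' @export
delta_params <- function(near = c(30, 47, 114, 130),
                         far = c(80, 97, 164, 180),
                         k = 0.35, scale = 1) {
  for (tup in list(near = near, far = far)) {
    if (length(tup) != 4 || any(tup < 0) || any(diff(tup) <= 0)) {
      stop("threshold tuples must satisfy 0 <= a < b < c < d", call. = FALSE)
    }
  }
  if (k < 0 || k > 1) stop("`k` must be in [0, 1]", call. = FALSE)
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  structure(list(near = near * scale, far = far * scale, k = k),
            class = "delta_params")
}

#' Weights of the confidence and positional terms
#'
#' The pattern objective averages, over the 32 tooth positions, the
#' weighted sum `omega_c * mu_c + omega_p * mu_p` of the detector
#' confidence and the positional relationship score. The weights must sum
#' to 1 so the objective stays in \[0, 1\].
#'
#' @param omega_c Weight of the confidence term (default 0.8).
#' @param omega_p Weight of the positional term (default 0.2).
#' @return An object of class `score_weights`.
#' @export
score_weights <- function(omega_c = 0.8, omega_p = 0.2) {
  if (omega_c < 0 || omega_p < 0 || abs(omega_c + omega_p - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(omega_c = omega_c, omega_p = omega_p),
            class = "score_weights")
}

#' Coordinate score between two tooth candidates
#'
#' Evaluates the trapezoidal coordinate score on the absolute horizontal
#' center distance between two candidates. `NA` distances encode a
#' missing tooth on either side and score `k`. Vectorized over
#' `distance` and `order`.
#'
#' @param distance Absolute difference of horizontal box centers, in
#'   pixels; `NA` if either candidate is the missing-tooth candidate.
#' @param order 1 for adjacent neighbors, 2 for second-order neighbors.
#' @param params A [delta_params()] object.
#' @return Scores in `{0} U [k, 1]`.
#' @examples
#' p <- delta_params()
#' delta_score(80, 1, p)    # 1: on the adjacent plateau
#' delta_score(20, 1, p)    # 0: centers implausibly close
#' delta_score(NA, 1, p)    # 0.35: missing neighbor
#' @export
delta_score <- function(distance, order = 1, params = delta_params()) {
  stopifnot(all(order %in% c(1, 2)))
  if (length(order) == 1) order <- rep(order, length(distance))
  a <- ifelse(order == 1, params$near[1], params$far[1])
  b <- ifelse(order == 1, params$near[2], params$far[2])
  cc <- ifelse(order == 1, params$near[3], params$far[3])
  d <- ifelse(order == 1, params$near[4], params$far[4])
  k <- params$k
  dx <- abs(distance)
  out <- numeric(length(dx))
  miss <- is.na(dx)
  out[miss] <- k
  i <- !miss
  out[i] <- ifelse(dx[i] < a[i], 0,
            ifelse(dx[i] < b[i], k + (1 - k) * (dx[i] - a[i]) / (b[i] - a[i]),
            ifelse(dx[i] <= cc[i], 1,
            ifelse(dx[i] <= d[i], 1 - (1 - k) * (dx[i] - cc[i]) / (d[i] - cc[i]),
                   0))))
  out
}

# Neighborhood bookkeeping: for each tooth x the up-to-four neighbors
# x + i, i in {-2, -1, 1, 2}, clipped to 1..32.  NBR_IDX[x, j] is the
# neighbor position or NA; NBR_ORD[x, j] the neighbor order |i|.
NBR_OFFSETS <- c(-2L, -1L, 1L, 2L)
NBR_IDX <- t(vapply(1:32, function(x) {
  y <- x + NBR_OFFSETS
  y[y < 1L | y > 32L] <- NA_integer_
  y
}, integer(4)))
NBR_ORD <- matrix(rep(c(2, 1, 1, 2), each = 32), nrow = 32)

neighbor_index <- function(restrict_omega_to_jaw = FALSE) {
  idx <- NBR_IDX
  if (restrict_omega_to_jaw) {
    same_jaw <- ((row(idx) - 1) %/% 16) == ((idx - 1) %/% 16)
    idx[!is.na(idx) & !same_jaw] <- NA_integer_
  }
  idx
}

# mu_p for every tooth given the 32 selected centers (NA = missing tooth).
positional_scores_all <- function(centers, params,
                                  restrict_omega_to_jaw = FALSE) {
  idx <- neighbor_index(restrict_omega_to_jaw)
  in_range <- !is.na(idx)
  dist <- matrix(NA_real_, 32, 4)
  self <- centers[row(idx)]
  nbr <- rep(NA_real_, length(idx))
  nbr[in_range] <- centers[idx[in_range]]
  dist[] <- abs(self - nbr)          # NA when either side missing
  sc <- matrix(delta_score(as.vector(dist), as.vector(NBR_ORD), params),
               32, 4)
  sc[!in_range] <- 0
  rowSums(sc) / rowSums(in_range)
}

#' Positional relationship score of one tooth in a pattern
#'
#' The positional score of tooth `x` is the mean coordinate score over its
#' neighborhood: the teeth at positions `x + i`, `i` in `{-2, -1, 1, 2}`,
#' that fall inside 1--32 (two neighbors at the arch ends, three next to
#' the ends, four elsewhere). First-order neighbors use the `near`
#' thresholds, second-order neighbors the `far` ones. By default the
#' neighborhood runs straight through positions 16/17 (the literal index
#' rule); `restrict_omega_to_jaw = TRUE` truncates it at the jaw boundary.
#'
#' @param cs A [candidate_set()].
#' @param ranks Integer vector of length 32 selecting one candidate rank
#'   (0 = missing) per tooth.
#' @param tooth Tooth position(s) 1--32 to score; default all.
#' @param params A [delta_params()] object.
#' @param restrict_omega_to_jaw Truncate neighborhoods at the 16/17
#'   boundary. Default `FALSE`.
#' @return Numeric vector of positional scores in \[0, 1\].
#' @export
positional_score <- function(cs, ranks, tooth = 1:32,
                             params = delta_params(),
                             restrict_omega_to_jaw = FALSE) {
  st <- pattern_state(cs, ranks, missing_conf = params$k)
  positional_scores_all(st$centers, params, restrict_omega_to_jaw)[tooth]
}

#' Combined pattern score
#'
#' The objective the candidate optimizer maximizes: the mean over the 32
#' tooth positions of `omega_c * mu_c + omega_p * mu_p`, where `mu_c` is
#' the detector confidence of the selected candidate (or `missing_conf`
#' for the missing-tooth choice) and `mu_p` its positional relationship
#' score. With weights summing to 1 and all inputs in \[0, 1\] the score
#' lies in \[0, 1\].
#'
#' @inheritParams positional_score
#' @param weights A [score_weights()] object.
#' @param missing_conf Confidence surrogate assigned to the rank-0
#'   missing-tooth candidate; defaults to `params$k`, the same neutral
#'   value the coordinate score uses for missing teeth.
#' @return The scalar pattern score.
#' @export
pattern_score <- function(cs, ranks, weights = score_weights(),
                          params = delta_params(),
                          missing_conf = params$k,
                          restrict_omega_to_jaw = FALSE) {
  if (missing_conf < 0 || missing_conf > 1) {
    stop("`missing_conf` must be in [0, 1]", call. = FALSE)
  }
  st <- pattern_state(cs, ranks, missing_conf)
  mu_p <- positional_scores_all(st$centers, params, restrict_omega_to_jaw)
  mean(weights$omega_c * st$conf + weights$omega_p * mu_p)
}
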