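#' Initial pattern: most confident candidate per tooth
#'
#' The search starts from the pattern that takes, for every tooth
#' position, the rank-1 (highest-confidence) candidate, or the rank-0
#' missing-tooth candidate where the detector produced nothing. This is
#' exactly what a detector pipeline without positional refinement would
#' report.
#'
#' @param cs A [candidate_set()].
#' @return Integer rank vector of length 32.
#' @export
initialize_pattern <- function(cs) {
  stopifnot(inherits(cs, "candidate_set"))
  as.integer(ifelse(cs$n > 0L, 1L, 0L))
}

# mu_p restricted to `teeth` (used for incremental rescoring of the
# 5-tooth window a single substitution can affect).
mu_p_for <- function(centers, teeth, params, idx) {
  out <- numeric(length(teeth))
  for (j in seq_along(teeth)) {
    x <- teeth[j]
    nb <- idx[x, ]
    ok <- !is.na(nb)
    d <- abs(centers[x] - centers[nb[ok]])
    out[j] <- sum(delta_score(d, NBR_ORD[x, ok], params)) / sum(ok)
  }
  out
}

#' Greedy candidate-pattern optimization
#'
#' Coordinate-ascent search over candidate patterns. Starting from the
#' highest-confidence initialization, the optimizer sweeps the tooth
#' positions 1 to 32; at each position it tries every candidate
#' (including "missing") in place of the current choice and evaluates the
#' full pattern score. Strict improvements are accepted; the search stops
#' after the first full sweep that accepts nothing. Because the score
#' strictly increases at every acceptance and patterns are finite, the
#' search always terminates, and its final score can never fall below the
#' initialization score.
#'
#' `sweep_mode` selects the acceptance discipline: `"immediate"`
#' (default) accepts each improving substitution as soon as it is found,
#' so later trials within the sweep see the updated pattern;
#' `"batch"` evaluates all substitutions against the sweep's starting
#' pattern and applies only the single best one per sweep. Both are exact
#' coordinate searches; they can differ only in the local optimum reached.
#'
#' @inheritParams pattern_score
#' @param sweep_mode `"immediate"` or `"batch"` (see Details).
#' @return An object of class `tooth_optim`: list with `ranks` (the
#'   optimized pattern), `score` (its pattern score), `initial_score`,
#'   `sweeps` (full passes performed), and `evaluations` (number of
#'   candidate substitutions scored).
#' @seealso [optimize_exhaustive()] for the global-optimum oracle.
#' @export
optimize_greedy <- function(cs, weights = score_weights(),
                            params = delta_params(),
                            missing_conf = params$k,
                            sweep_mode = c("immediate", "batch"),
                            restrict_omega_to_jaw = FALSE) {
  sweep_mode <- match.arg(sweep_mode)
  ranks <- initialize_pattern(cs)
  idx <- neighbor_index(restrict_omega_to_jaw)
  w_c <- weights$omega_c; w_p <- weights$omega_p

  st <- pattern_state(cs, ranks, missing_conf)
  centers <- st$centers; conf <- st$conf
  mu_p <- positional_scores_all(centers, params, restrict_omega_to_jaw)
  s_max <- mean(w_c * conf + w_p * mu_p)
  initial_score <- s_max

  evals <- 0L
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    improved <- FALSE
    if (sweep_mode == "batch") {
      base <- list(ranks = ranks, centers = centers, conf = conf,
                   mu_p = mu_p, score = s_max)
      best <- NULL
    }
    for (x in 1:32) {
      if (cs$n[x] == 0L) next
      affected <- intersect((x - 2L):(x + 2L), 1:32)
      for (r in 0:cs$n[x]) {
        if (r == ranks[x]) next
        evals <- evals + 1L
        new_center <- if (r == 0L) NA_real_ else cs$centers[[x]][r]
        new_conf <- if (r == 0L) missing_conf else cs$confidences[[x]][r]
        centers_try <- centers
        centers_try[x] <- new_center
        mu_try <- mu_p_for(centers_try, affected, params, idx)
        s_try <- s_max +
          (w_c * (new_conf - conf[x]) +
           w_p * (sum(mu_try) - sum(mu_p[affected]))) / 32
        if (sweep_mode == "immediate") {
          if (s_try > s_max) {
            ranks[x] <- r
            centers <- centers_try
            conf[x] <- new_conf
            mu_p[affected] <- mu_try
            # re-anchor the score to kill incremental round-off
            s_max <- mean(w_c * conf + w_p * mu_p)
            improved <- TRUE
          }
        } else if (s_try > base$score && (is.null(best) || s_try > best$score)) {
          best <- list(x = x, r = r, score = s_try)
        }
      }
    }
    if (sweep_mode == "batch") {
      if (!is.null(best)) {
        x <- best$x; r <- best$r
        ranks[x] <- r
        centers[x] <- if (r == 0L) NA_real_ else cs$centers[[x]][r]
        conf[x] <- if (r == 0L) missing_conf else cs$confidences[[x]][r]
        affected <- intersect((x - 2L):(x + 2L), 1:32)
        mu_p[affected] <- mu_p_for(centers, affected, params, idx)
        s_max <- mean(w_c * conf + w_p * mu_p)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  structure(list(ranks = ranks, score = s_max,
                 initial_score = initial_score,
                 sweeps = sweeps, evaluations = evals),
            class = "tooth_optim")
}

#' Exhaustive pattern search (test oracle)
#'
#' Enumerates all `prod(N(x) + 1)` candidate combinations and returns the
#' globally optimal pattern under the pattern score. Intended as the
#' ground-truth oracle for verifying the greedy search on small
#' instances; the combination count is capped to keep it honest about
#' what it can enumerate. Ties on the maximal score are broken toward the
#' lexicographically smallest rank vector (teeth 1 to 32 most significant,
#' rank 0 first), which makes the result independent of candidate input
#' order.
#'
#' @inheritParams pattern_score
#' @param max_combinations Refuse to enumerate more than this many
#'   patterns (default `1e6`).
#' @return A `tooth_optim` object (with `sweeps = NA`).
#' @export
optimize_exhaustive <- function(cs, weights = score_weights(),
                                params = delta_params(),
                                missing_conf = params$k,
                                max_combinations = 1e6,
                                restrict_omega_to_jaw = FALSE) {
  stopifnot(inherits(cs, "candidate_set"))
  n_comb <- prod(cs$n + 1)
  if (n_comb > max_combinations) {
    stop("search space has ", format(n_comb, big.mark = ","),
         " combinations, above the cap of ",
         format(max_combinations, big.mark = ","), call. = FALSE)
  }
  w_c <- weights$omega_c; w_p <- weights$omega_p
  vary <- which(cs$n > 0L)
  ranks <- integer(32)
  st <- pattern_state(cs, ranks, missing_conf)
  centers <- st$centers; conf <- st$conf

  score_of <- function() {
    mu_p <- positional_scores_all(centers, params, restrict_omega_to_jaw)
    mean(w_c * conf + w_p * mu_p)
  }
  best_ranks <- ranks
  best_score <- score_of()
  evals <- 1L
  if (length(vary)) {
    repeat {
      # advance mixed-radix counter: last varying tooth fastest, so
      # patterns appear in lexicographic rank-vector order
      j <- length(vary)
      while (j >= 1L) {
        x <- vary[j]
        if (ranks[x] < cs$n[x]) {
          ranks[x] <- ranks[x] + 1L
          centers[x] <- cs$centers[[x]][ranks[x]]
          conf[x] <- cs$confidences[[x]][ranks[x]]
          break
        }
        ranks[x] <- 0L
        centers[x] <- NA_real_
        conf[x] <- missing_conf
        j <- j - 1L
      }
      if (j < 1L) break
      s <- score_of()
      evals <- evals + 1L
      if (s > best_score) {    # strict: first (lexicographically
        best_score <- s        # smallest) maximizer is kept on ties
        best_ranks <- ranks
      }
    }
  }
  st0 <- pattern_state(cs, initialize_pattern(cs), missing_conf)
  init_score <- mean(w_c * st0$conf +
                     w_p * positional_scores_all(st0$centers, params,
                                                 restrict_omega_to_jaw))
  structure(list(ranks = best_ranks, score = best_score,
                 initial_score = init_score,
                 sweeps = NA_integer_, evaluations = evals),
            class = "tooth_optim")
}

#' @export
print.tooth_optim <- function(x, ...) {
  cat("<tooth_optim> score", format(x$score, digits = 6),
      "(initial", format(x$initial_score, digits = 6), ")\n")
  cat("  teeth present:", sum(x$ranks > 0), "of 32;",
      "sweeps:", x$sweeps, "; evaluations:", x$evaluations, "\n")
  invisible(x)
}
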