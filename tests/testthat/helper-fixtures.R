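# Fixture builders and independent naive oracles.  The oracles re-derive
# the scores with plain nested loops and their own piecewise code, on
# purpose sharing nothing with the package's scoring engine.

# one detection row
det_row <- function(tooth, cx, conf, w = 60, h = 100, cy = 380) {
  data.frame(tooth = tooth, x_min = cx - w / 2, y_min = cy - h / 2,
             x_max = cx + w / 2, y_max = cy + h / 2, confidence = conf)
}

# candidate set with exactly one candidate per non-NA center
cs_from_centers <- function(centers, confs = rep(0.9, 32)) {
  rows <- list()
  for (x in 1:32) {
    if (!is.na(centers[x])) {
      rows[[length(rows) + 1L]] <- det_row(x, centers[x], confs[x])
    }
  }
  candidate_set(if (length(rows)) do.call(rbind, rows) else NULL)
}

# an ideal arch: 32 teeth, adjacent centers 80 px apart (score plateau)
ideal_centers <- function() {
  up <- seq(1600, by = -80, length.out = 16)       # tooth 1 at the right
  lo <- seq(up[16], by = 80, length.out = 16)      # tooth 17 under 16
  c(up, lo)
}

# random small instance: `teeth` positions get 0..max_cand candidates
# scattered around an ideal arch
random_instance <- function(seed, teeth = 3:8, max_cand = 3,
                            pos_sd = 40) {
  set.seed(seed)
  base <- ideal_centers()
  rows <- list()
  for (t in teeth) {
    n <- sample(0:max_cand, 1)
    for (j in seq_len(n)) {
      rows[[length(rows) + 1L]] <-
        det_row(t, base[t] + rnorm(1, 0, pos_sd), runif(1, 0.3, 1))
    }
  }
  candidate_set(if (length(rows)) do.call(rbind, rows) else NULL)
}

# --- independent oracle ------------------------------------------------

naive_delta <- function(c1, c2, ord, k = 0.35) {
  if (is.na(c1) || is.na(c2)) return(k)
  t <- if (ord == 1) c(30, 47, 114, 130) else c(80, 97, 164, 180)
  dx <- abs(c1 - c2)
  if (dx < t[1]) 0
  else if (dx < t[2]) k + (1 - k) * (dx - t[1]) / (t[2] - t[1])
  else if (dx <= t[3]) 1
  else if (dx <= t[4]) 1 - (1 - k) * (dx - t[3]) / (t[4] - t[3])
  else 0
}

# term-by-term recomputation of the pattern objective from selected
# centers/confidences (NA center = missing tooth)
naive_pattern_score <- function(centers, confs, omega_c = 0.8,
                                omega_p = 0.2, k = 0.35,
                                missing_conf = k) {
  total <- 0
  for (x in 1:32) {
    acc <- 0; cnt <- 0
    for (i in c(-2L, -1L, 1L, 2L)) {
      y <- x + i
      if (y < 1 || y > 32) next
      cnt <- cnt + 1
      acc <- acc + naive_delta(centers[x], centers[y], abs(i), k)
    }
    mu_p <- acc / cnt
    mu_c <- if (is.na(centers[x])) missing_conf else confs[x]
    total <- total + omega_c * mu_c + omega_p * mu_p
  }
  total / 32
}

# selected centers/confidences for a rank vector, read straight off the
# candidate_set tables (independent of pattern_state)
selection_of <- function(cs, ranks) {
  centers <- rep(NA_real_, 32); confs <- rep(NA_real_, 32)
  for (x in 1:32) {
    if (ranks[x] > 0) {
      row <- cs$detections[cs$detections$tooth == x &
                           cs$detections$rank == ranks[x], ]
      centers[x] <- (row$x_min + row$x_max) / 2
      confs[x] <- row$confidence
    }
  }
  list(centers = centers, confs = confs)
}

noise_free_config <- function(seed = 1) {
  sim_config(p_missdetect = 0, p_duplicate = 0, p_label_swap = 0,
             spurious_rate = 0, seed = seed)
}
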