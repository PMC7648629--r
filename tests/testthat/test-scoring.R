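test_that("coordinate score reproduces the piecewise trapezoid", {
  p <- delta_params()
  expect_equal(delta_score(NA, 1, p), 0.35)                 # missing -> k
  expect_equal(delta_score(20, 1, p), 0)                    # below a
  expect_equal(delta_score(80, 1, p), 1)                    # plateau
  expect_equal(delta_score(38.5, 1, p),
               0.35 + 0.65 * (38.5 - 30) / 17, tolerance = 1e-14)
  expect_equal(delta_score(120, 1, p),
               1 - 0.65 * (120 - 114) / 16, tolerance = 1e-14)
  expect_equal(delta_score(120, 2, p), 1)                   # far plateau
  expect_equal(delta_score(200, 2, p), 0)                   # beyond d

  # closed ramp ends: a -> k, b -> 1, c -> 1, d -> k
  expect_equal(delta_score(c(30, 47, 114, 130), 1, p),
               c(0.35, 1, 1, 0.35))
})

test_that("coordinate score is symmetric, bounded and order-driven", {
  p <- delta_params()
  dx <- c(seq(0, 250, by = 0.5), NA)
  v1 <- delta_score(dx, 1, p)
  expect_true(all(v1 == 0 | (v1 >= p$k - 1e-12 & v1 <= 1 + 1e-12)))
  # only |distance| matters
  expect_equal(delta_score(-dx, 1, p), v1)
  # naive oracle agreement across the whole range, both orders
  for (ord in 1:2) {
    expect_equal(delta_score(dx, ord, p),
                 vapply(dx, function(d) naive_delta(0, d, ord), 0),
                 tolerance = 1e-14)
  }
})

test_that("scaled and custom parameters reshape the trapezoid", {
  p2 <- delta_params(scale = 2)
  expect_equal(delta_score(160, 1, p2), 1)   # plateau doubled
  expect_equal(delta_score(80, 1, p2), delta_score(40, 1, delta_params()))
  expect_error(delta_params(near = c(47, 30, 114, 130)), "a < b < c < d")
  expect_error(delta_params(k = 1.2), "k")
  expect_error(score_weights(0.8, 0.5), "sum to 1")
})

test_that("positional score averages the in-range neighborhood", {
  centers <- ideal_centers()
  cs <- cs_from_centers(centers)
  ranks <- initialize_pattern(cs)
  # interior tooth with all four neighbors at plateau distances
  expect_equal(positional_score(cs, ranks, tooth = 5), 1)
  # arch end: only two neighbors; one at plateau, one missing
  centers3 <- centers; centers3[3] <- NA
  cs3 <- cs_from_centers(centers3)
  expect_equal(positional_score(cs3, initialize_pattern(cs3), tooth = 1),
               (1 + 0.35) / 2)
  # fully missing neighborhood scores k everywhere
  cs0 <- candidate_set(NULL)
  expect_equal(positional_score(cs0, rep(0L, 32), tooth = 5), 0.35)
})

test_that("jaw-restricted neighborhoods stop at the 16/17 boundary", {
  cs <- cs_from_centers(ideal_centers())
  ranks <- initialize_pattern(cs)
  # default: tooth 16 sees 17 and 18 across the boundary at near-zero
  # and one-spacing distances, pulling its score down
  full <- positional_score(cs, ranks, tooth = 16)
  jaw <- positional_score(cs, ranks, tooth = 16,
                          restrict_omega_to_jaw = TRUE)
  expect_lt(full, jaw)
  expect_equal(jaw, 1)  # within-jaw neighbors 14, 15 both at plateau
  # interior teeth unaffected
  expect_equal(positional_score(cs, ranks, tooth = 8,
                                restrict_omega_to_jaw = TRUE),
               positional_score(cs, ranks, tooth = 8))
})

test_that("pattern score matches the naive term-by-term oracle", {
  # closed-form checks
  cs <- cs_from_centers(ideal_centers(), confs = rep(1, 32))
  ranks <- initialize_pattern(cs)
  # jaw-restricted ideal arch: mu_c = mu_p = 1 everywhere, any weights
  for (w in list(score_weights(0.8, 0.2), score_weights(0.5, 0.5))) {
    expect_equal(pattern_score(cs, ranks, w,
                               restrict_omega_to_jaw = TRUE), 1)
  }
  # all-missing pattern scores k when missing_conf = k
  cs0 <- candidate_set(NULL)
  expect_equal(pattern_score(cs0, rep(0L, 32)), 0.35)

  # random instances vs independent recomputation, both weight sets
  for (seed in 1:25) {
    csr <- random_instance(seed, teeth = sample(1:32, 8), max_cand = 3)
    ranks <- vapply(1:32, function(x) sample(0:csr$n[x], 1), 0L)
    sel <- selection_of(csr, ranks)
    for (w in list(c(0.8, 0.2), c(0.5, 0.5))) {
      expect_equal(
        pattern_score(csr, ranks, score_weights(w[1], w[2])),
        naive_pattern_score(sel$centers, sel$confs, w[1], w[2]),
        tolerance = 1e-12)
    }
  }
})

test_that("pattern score is bounded and monotone in confidence", {
  for (seed in 1:10) {
    cs <- random_instance(seed, teeth = 1:12, max_cand = 2)
    ranks <- initialize_pattern(cs)
    s <- pattern_score(cs, ranks)
    expect_gte(s, 0); expect_lte(s, 1)
    # raise one selected candidate's confidence: score cannot drop
    x <- which(ranks > 0)[1]
    if (!is.na(x)) {
      det <- cs$detections
      i <- which(det$tooth == x & det$rank == ranks[x])
      det$confidence[i] <- min(1, det$confidence[i] + 0.1)
      cs2 <- candidate_set(det[, names(det) != "rank"])
      # re-ranking may renumber; rescore the same physical selection
      r2 <- vapply(1:32, function(t) {
        if (ranks[t] == 0) return(0L)
        old <- cs$detections[cs$detections$tooth == t &
                             cs$detections$rank == ranks[t], ]
        cx <- (old$x_min + old$x_max) / 2
        rows <- cs2$detections[cs2$detections$tooth == t, ]
        as.integer(rows$rank[which.min(abs((rows$x_min + rows$x_max) / 2 - cx))])
      }, 0L)
      expect_gte(pattern_score(cs2, r2), s - 1e-12)
    }
  }
})
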