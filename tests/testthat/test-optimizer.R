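test_that("initialization takes the most confident candidate per tooth", {
  det <- rbind(det_row(1, 500, 0.7), det_row(1, 600, 0.95),
               det_row(7, 900, 0.4))
  cs <- candidate_set(det)
  ranks <- initialize_pattern(cs)
  expect_equal(ranks[1], 1L)
  sel <- pattern_detections(cs, ranks)
  expect_equal(sel$confidence[sel$tooth == 1], 0.95)
  expect_equal(sel$confidence[sel$tooth == 7], 0.4)   # single candidate
  expect_equal(sum(ranks > 0), 2)
  expect_equal(initialize_pattern(candidate_set(NULL)), rep(0L, 32))
})

test_that("greedy search rejects a displaced duplicate in a clean arch", {
  centers <- ideal_centers()
  centers[11:32] <- NA  # partial arch keeps the oracle's search space small
  cs_clean <- cs_from_centers(centers, confs = rep(0.9, 32))
  det <- cs_clean$detections[, names(cs_clean$detections) != "rank"]
  # displaced duplicate of tooth 1 (center shifted half a tooth away)
  det <- rbind(det, det_row(1, centers[1] + 40, 0.7))
  cs <- candidate_set(det)
  res <- optimize_greedy(cs)
  sel <- pattern_detections(cs, res$ranks)
  expect_equal(sel$confidence[sel$tooth == 1], 0.9)
  # exhaustive oracle agrees on this instance
  ex <- optimize_exhaustive(cs, max_combinations = 1e7)
  expect_equal(res$ranks, ex$ranks)
  expect_equal(res$score, ex$score, tolerance = 1e-12)
})

test_that("zero-noise instances are already optimal at initialization", {
  cs <- cs_from_centers(ideal_centers(), confs = rep(0.95, 32))
  res <- optimize_greedy(cs)
  expect_equal(res$ranks, initialize_pattern(cs))
  expect_equal(res$score, res$initial_score)
  expect_equal(res$sweeps, 1L)  # single sweep, nothing accepted
})

test_that("greedy never beats the exhaustive oracle and usually matches it", {
  n_match <- 0L
  for (seed in 1:60) {
    cs <- random_instance(seed, teeth = 3:8, max_cand = 3)
    g <- optimize_greedy(cs)
    ex <- optimize_exhaustive(cs)
    expect_lte(g$score, ex$score + 1e-12)
    expect_gte(g$score, g$initial_score - 1e-12)
    # reported scores are re-checkable against pattern_score
    expect_equal(g$score, pattern_score(cs, g$ranks), tolerance = 1e-10)
    expect_equal(ex$score, pattern_score(cs, ex$ranks), tolerance = 1e-10)
    if (abs(g$score - ex$score) <= 1e-12) n_match <- n_match + 1L
  }
  expect_gte(n_match / 60, 0.8)
})

test_that("batch sweep mode also terminates at a no-worse-than-initial optimum", {
  for (seed in c(2, 9, 17)) {
    cs <- random_instance(seed, teeth = 2:9, max_cand = 3)
    b <- optimize_greedy(cs, sweep_mode = "batch")
    ex <- optimize_exhaustive(cs)
    expect_gte(b$score, b$initial_score - 1e-12)
    expect_lte(b$score, ex$score + 1e-12)
    expect_equal(b$score, pattern_score(cs, b$ranks), tolerance = 1e-10)
  }
})

test_that("exhaustive search is order-invariant and tie-breaks deterministically", {
  cs <- random_instance(11, teeth = 4:7, max_cand = 2)
  det <- cs$detections[, names(cs$detections) != "rank"]
  ex1 <- optimize_exhaustive(candidate_set(det))
  ex2 <- optimize_exhaustive(candidate_set(det[rev(seq_len(nrow(det))), ]))
  expect_equal(ex1$ranks, ex2$ranks)
  expect_equal(ex1$score, ex2$score)

  # all-missing-only set: unique pattern, score k
  cs0 <- candidate_set(NULL)
  ex0 <- optimize_exhaustive(cs0)
  expect_equal(ex0$ranks, rep(0L, 32))
  expect_equal(ex0$score, 0.35)

  # combination cap is enforced with the count in the message
  big <- random_instance(3, teeth = 1:20, max_cand = 3)
  expect_error(optimize_exhaustive(big, max_combinations = 100),
               "combinations")
})

test_that("optimizer output is deterministic", {
  cs <- random_instance(21, teeth = 1:10, max_cand = 3)
  a <- optimize_greedy(cs)
  b <- optimize_greedy(cs)
  expect_identical(a, b)
})
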