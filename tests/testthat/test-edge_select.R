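test_that("edge ICC matches the one-way ANOVA decomposition", {
  # retest = test with across-subject variance: every ICC is 1 (MSW = 0)
  test <- matrix(rnorm(5 * 4), 5, 4)
  r <- edge_icc(test, test)
  expect_equal(r$per_edge_icc, rep(1, 4))

  # two subjects, one edge, test/retest (0,1) and (1,0): MSA = 0,
  # MSW = 0.5, formula gives -1
  r2 <- edge_icc(matrix(c(0, 1), 2, 1), matrix(c(1, 0), 2, 1))
  expect_equal(r2$per_edge_icc, -1)
  expect_equal(r2$msa_per_edge, 0)
  expect_equal(r2$msw_per_edge, 0.5)

  # random data: per-edge oracle via stats::aov
  set.seed(14)
  te <- matrix(rnorm(20 * 12), 20, 12) +
    matrix(rnorm(20), 20, 12) # subject effects
  re <- te + matrix(rnorm(20 * 12, 0, 0.5), 20, 12)
  te <- te + matrix(rnorm(20 * 12, 0, 0.5), 20, 12)
  r3 <- edge_icc(te, re)
  for (e in c(1, 5, 12)) {
    expect_equal(r3$per_edge_icc[e], oracle_icc_aov(te[, e], re[, e]),
                 tolerance = 1e-9)
  }

  # invariance to adding a common constant to one edge
  te2 <- te; re2 <- re
  te2[, 3] <- te2[, 3] + 100; re2[, 3] <- re2[, 3] + 100
  expect_equal(edge_icc(te2, re2)$per_edge_icc[3], r3$per_edge_icc[3],
               tolerance = 1e-9)
})

test_that("zero-variance edges get missing ICC and rank last", {
  te <- cbind(rnorm(6), rep(2, 6), rnorm(6))
  re <- cbind(rnorm(6), rep(2, 6), rnorm(6))
  r <- edge_icc(te, re)
  expect_true(is.na(r$per_edge_icc[2]))
  expect_equal(r$edge_order[3], 2L) # the NA edge is ordered last
})

test_that("IR curves are consistent with the full-kinectome fingerprint", {
  sim <- simulate_planted_edges(n_subjects = 10, n_edges = 30,
                                n_signature = 8, seed = 2)
  icc <- edge_icc(sim$test, sim$retest)
  curve <- ir_curve(sim$test, sim$retest, icc$edge_order)
  expect_equal(curve$edge_counts, 3:30)
  expect_true(all(curve$ir_values >= 0 & curve$ir_values <= 1))

  full_ir <- fingerprint_scores(
    identifiability_matrix(sim$test, sim$retest)
  )$ir
  expect_equal(curve$ir_values[length(curve$ir_values)], full_ir)

  expect_error(ir_curve(sim$test, sim$retest, 1:29), "permutation")
})

test_that("noiseless cohorts keep IR = 1 along the whole curve", {
  sim <- simulate_planted_edges(n_subjects = 8, n_edges = 40,
                                n_signature = 40, noise_sd = 0, seed = 3)
  curve <- ir_curve(sim$test, sim$retest, seq_len(40))
  expect_true(all(curve$ir_values == 1))
})

test_that("ICC ordering finds planted signature edges quickly", {
  sim <- simulate_planted_edges(seed = 6) # 20 signatures among 210
  icc <- edge_icc(sim$test, sim$retest)
  # the top-ranked edges are the planted ones
  expect_true(all(icc$edge_order[1:10] %in% sim$signature_edges))

  curve <- ir_curve(sim$test, sim$retest, icc$edge_order)
  eoi <- edges_of_interest(curve, ir_threshold = 0.99)
  expect_lte(attr(eoi, "n_edges"), 25)
  expect_true(all(eoi %in% sim$signature_edges))

  band <- null_ir_curves(sim$test, sim$retest, n_null = 40, seed = 8)
  expect_true(all(curve$ir_values >= band$null_mean))
  # determinism of the null band
  band2 <- null_ir_curves(sim$test, sim$retest, n_null = 40, seed = 8)
  expect_identical(band$null_curves, band2$null_curves)
})

test_that("edges_of_interest handles thresholds and misses", {
  curve <- list(
    edge_counts = 3:10,
    ir_values = c(.2, .4, .5, .7, .95, 1, 1, 1),
    edge_order = 10:1
  )
  class(curve) <- "ir_curve"
  eoi <- edges_of_interest(curve, ir_threshold = 0.99)
  expect_equal(attr(eoi, "n_edges"), 8) # first count with IR > .99
  expect_equal(as.integer(eoi), 10:3)

  # threshold 0: the minimum count wins
  expect_equal(attr(edges_of_interest(curve, 0), "n_edges"), 3)
  # linear-scan oracle on a monotone curve
  expect_equal(
    attr(edges_of_interest(curve, 0.6), "n_edges"),
    curve$edge_counts[min(which(curve$ir_values > 0.6))]
  )

  curve$ir_values <- rep(0.5, 8)
  expect_warning(out <- edges_of_interest(curve), "never exceeds")
  expect_length(out, 0)
})

test_that("node occurrence flags concentrated markers, not uniform ones", {
  idx <- edge_index(21)
  star <- which(idx$i == 1 | idx$j == 1)[1:15] # all edges touch marker 1
  occ <- node_occurrence_significance(list(star), n_markers = 21,
                                      n_null = 2000, seed = 3)
  expect_true(occ$significant[1])
  expect_equal(occ$counts[1], 15)

  # uniformly random edge sets: false-positive rate near the nominal 1 %
  set.seed(9)
  flags <- replicate(200, {
    s <- sample.int(210, 25)
    occ <- node_occurrence_significance(list(s), n_markers = 21,
                                        n_null = 500,
                                        seed = sample.int(1e6, 1))
    mean(occ$significant)
  })
  expect_lt(mean(flags), 0.05)
})
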