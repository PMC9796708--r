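test_that("kinectome entries are pairwise Pearson correlations", {
  set.seed(11)
  n_frames <- 120
  series <- matrix(rnorm(n_frames * 21), n_frames, 21)
  colnames(series) <- default_marker_set()$label
  k <- build_kinectome(series, subject_id = "S1")

  # brute-force covariance/variance oracle, entry by entry
  for (pair in list(c(1, 2), c(3, 17), c(20, 21), c(5, 5))) {
    i <- pair[1]; j <- pair[2]
    num <- mean((series[, i] - mean(series[, i])) *
                  (series[, j] - mean(series[, j])))
    den <- sqrt(mean((series[, i] - mean(series[, i]))^2) *
                  mean((series[, j] - mean(series[, j]))^2))
    expect_equal(k$matrix[i, j], num / den, tolerance = 1e-12)
  }
  expect_true(isSymmetric(k$matrix))
  expect_equal(unname(diag(k$matrix)), rep(1, 21))
})

test_that("degenerate series give the documented extremes and errors", {
  x <- sin((1:50) / 5)
  same <- cbind(a = x, b = x, c = x)
  expect_equal(unname(build_kinectome(same)$matrix), matrix(1, 3, 3))

  alt <- cbind(a = x, b = -x, c = x, d = -x)
  m <- build_kinectome(alt)$matrix
  expect_equal(unname(m), outer(c(1, -1, 1, -1), c(1, -1, 1, -1)))

  expect_error(build_kinectome(cbind(a = x, b = rep(1, 50))), "b")
})

test_that("kinectomes are invariant to affine rescaling of any series", {
  set.seed(3)
  series <- matrix(rnorm(100 * 5), 100, 5)
  colnames(series) <- paste0("M", 1:5)
  k1 <- build_kinectome(series)
  series[, 2] <- 3.7 * series[, 2] - 11
  series[, 5] <- 0.02 * series[, 5] + 4
  k2 <- build_kinectome(series)
  expect_lt(max(abs(k1$matrix - k2$matrix)), 1e-12)
})

test_that("a trial yields exactly six kinectomes (2 quantities x 3 axes)", {
  ch <- generate_cohort(cohort_spec(2, "healthy", seed = 9))
  ks <- trial_kinectomes(ch$trials[[1]], filter_policy = test_filter)
  expect_length(ks, 6)
  expect_setequal(
    names(ks),
    c(outer(c("acceleration", "jerk"), c("ML", "AP", "V"), paste, sep = "."))
  )
  expect_true(all(vapply(ks, function(k) nrow(k$matrix) == 21, logical(1))))
})

test_that("vectorize returns the row-major upper triangle and round-trips", {
  m3 <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3, 3)
  v <- vectorize(m3)
  expect_equal(as.numeric(v), c(.1, .2, .3))

  set.seed(5)
  series <- matrix(rnorm(120 * 21), 120, 21)
  colnames(series) <- default_marker_set()$label
  k <- build_kinectome(series)
  v <- vectorize(k)
  expect_length(v, 210)
  idx <- attr(v, "edge_index")
  expect_equal(nrow(idx), 210)
  expect_true(all(idx$i < idx$j))
  expect_equal(unvectorize(v, labels = k$labels), k$matrix, tolerance = 1e-15)

  asym <- m3; asym[1, 2] <- .5
  expect_error(vectorize(asym), "symmetric")
})

test_that("group edge statistics match element-wise computation", {
  set.seed(8)
  ks <- lapply(1:10, function(i) {
    series <- matrix(rnorm(60 * 4), 60, 4)
    colnames(series) <- paste0("M", 1:4)
    build_kinectome(series, subject_id = paste0("S", i),
                    quantity = "acceleration", axis = "ML")
  })
  mats <- simplify2array(lapply(ks, function(k) k$matrix))
  expect_equal(unname(group_edge_stats(ks, "mean")),
               unname(apply(mats, c(1, 2), mean)))
  expect_equal(unname(group_edge_stats(ks, "sd")),
               unname(apply(mats, c(1, 2), sd)))

  expect_equal(max(group_edge_stats(ks[c(1, 1, 1)], "sd")), 0)
  ks[[2]]$axis <- "AP"
  expect_error(group_edge_stats(ks, "mean"), "mix")
})

test_that("permutation test: null difference, floor p, and determinism", {
  a <- c(1, 2, 3, 4)
  same <- permutation_compare(a, a, n_perm = 200, seed = 1)
  expect_equal(same$observed_stat, 0)
  expect_equal(same$p_value, 1)

  # disjoint groups: p at the Monte-Carlo floor. With n = 3 + 3 only
  # choose(6,3) = 20 label assignments exist; the exhaustive null contains
  # exactly 2/20 assignments with |diff| >= observed, so p converges to
  # ~0.1 for large n_perm and to the +1-corrected floor when all
  # permutations are distinct draws at small n_perm.
  p <- permutation_compare(c(0, 0, 0), c(100, 100, 100),
                           n_perm = 2000, seed = 2)
  exhaustive <- 2 / 20 # only the two extreme assignments reach the observed
  expect_lt(abs(p$p_value - exhaustive), 0.03)

  r1 <- permutation_compare(1:5, 2:6, n_perm = 300, seed = 7)
  r2 <- permutation_compare(1:5, 2:6, n_perm = 300, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$null_stats, r2$null_stats)

  expect_error(permutation_compare(1:3, numeric(0)), "non-empty")
  expect_error(permutation_compare(1:3, 1:3, n_perm = 0), "n_perm")
})

test_that("Bonferroni cutoffs reproduce the 6- and 18-test thresholds", {
  expect_equal(bonferroni_cutoff(6), 0.05 / 6)
  expect_equal(round(bonferroni_cutoff(6), 4), 0.0083)
  expect_equal(round(bonferroni_cutoff(18), 4), 0.0028)
})
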