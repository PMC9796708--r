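test_that("modularity Q matches hand values and the double-loop oracle", {
  A <- two_triangle_graph()
  # one community covering everything always gives Q = 0
  expect_equal(modularity_q(A, rep(0, 6)), 0, tolerance = 1e-12)
  # the two triangles: Q = 0.5 by direct evaluation of the formula
  expect_equal(modularity_q(A, c(0, 0, 0, 1, 1, 1)), 0.5, tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:25) {
    n <- sample(6:8, 1)
    A <- random_adjacency(n)
    if (sum(A) == 0) next
    comm <- sample(0:2, n, replace = TRUE)
    expect_equal(modularity_q(A, comm), oracle_modularity_q(A, comm),
                 tolerance = 1e-9)
  }

  expect_error(modularity_q(matrix(0, 3, 3), c(0, 0, 0)), "zero total weight")
  expect_error(modularity_q(matrix(-1, 2, 2), c(0, 1)), "negative")
})

test_that("Louvain finds the exhaustive optimum on small graphs", {
  A <- two_triangle_graph()
  p <- louvain(A, seed = 1)
  expect_equal(length(unique(p$community_id)), 2)
  expect_equal(p$q_value, 0.5, tolerance = 1e-12)
  expect_equal(p$community_id[1:3], rep(p$community_id[1], 3))

  # same seed twice: identical partition
  expect_identical(louvain(A, seed = 5)$community_id,
                   louvain(A, seed = 5)$community_id)

  set.seed(33)
  for (rep in 1:10) {
    n <- sample(6:7, 1)
    A <- random_adjacency(n, density = 0.8)
    if (sum(A) == 0) next
    best <- oracle_max_modularity(A)
    got <- louvain(A, seed = rep)$q_value
    expect_lte(got, best + 1e-9)
  }

  # complete graph: every partition's Q <= exhaustive max, and Louvain
  # respects that bound
  K6 <- matrix(1, 6, 6); diag(K6) <- 0
  expect_lte(louvain(K6, seed = 2)$q_value, oracle_max_modularity(K6) + 1e-9)
})

test_that("consensus clustering reaches a stable partition deterministically", {
  A <- two_triangle_graph()
  single <- louvain(A, seed = 3)
  cons <- consensus_cluster(A, n_iter = 20, seed = 3)
  expect_equal(adjusted_rand(cons$community_id, single$community_id), 1)
  expect_equal(cons$q_value, 0.5, tolerance = 1e-12)

  # ambiguous node bridging two cliques still converges to a binary
  # co-assignment
  A2 <- matrix(0, 7, 7)
  A2[1:3, 1:3] <- 1; A2[5:7, 5:7] <- 1; diag(A2) <- 0
  A2[4, c(3, 5)] <- A2[c(3, 5), 4] <- 0.5
  cons2 <- consensus_cluster(A2, n_iter = 30, seed = 9)
  expect_length(cons2$community_id, 7)

  expect_identical(consensus_cluster(A, n_iter = 15, seed = 11)$community_id,
                   consensus_cluster(A, n_iter = 15, seed = 11)$community_id)
})

test_that("allegiance counts co-assignments and ignores label permutations", {
  p1 <- c(0, 0, 1, 1)
  p2 <- c(0, 0, 0, 1)
  alg <- allegiance(list(p1, p2))
  expect_equal(alg$n_partitions, 2)
  expect_equal(alg$matrix[1, 2], 1)   # together in both
  expect_equal(alg$matrix[2, 3], 0.5) # together in one
  expect_equal(unname(diag(alg$matrix)), rep(1, 4))

  # relabeling communities changes nothing
  p2_relab <- c(7, 7, 7, 2)
  expect_equal(allegiance(list(p1, p2))$matrix,
               allegiance(list(p1, p2_relab))$matrix)

  # brute-force pair counting on many random partitions
  set.seed(13)
  parts <- lapply(1:100, function(i) sample(0:3, 10, replace = TRUE))
  alg <- allegiance(parts)$matrix
  for (pair in list(c(1, 2), c(4, 9), c(5, 10))) {
    i <- pair[1]; j <- pair[2]
    expect_equal(alg[i, j],
                 mean(vapply(parts, function(p) p[i] == p[j], logical(1))))
  }

  expect_error(allegiance(list(c(0, 1), c(0, 1, 2))), "for 2 nodes")
})

test_that("group communities recover planted structure from allegiance", {
  # identical partitions: recovered exactly
  p <- c(0, 0, 1, 1, 2, 2)
  alg <- allegiance(lapply(1:10, function(i) p))
  rec <- group_communities(alg, seed = 2)
  expect_equal(adjusted_rand(rec$community_id, p), 1)

  # synthetic healthy cohort: planted ML modules recovered, with left and
  # right homologous leg markers sharing a community
  ch <- generate_cohort(cohort_spec(12, "healthy", seed = 31))
  ks <- cohort_kinectomes(ch, "acceleration", "ML")
  parts <- lapply(seq_along(ks$test), function(i) {
    louvain(prepare_adjacency(ks$test[[i]]), seed = i)
  })
  ksj <- cohort_kinectomes(ch, "jerk", "ML")
  parts <- c(parts, lapply(seq_along(ksj$test), function(i) {
    louvain(prepare_adjacency(ksj$test[[i]]), seed = 100 + i)
  }))
  rec <- group_communities(allegiance(parts), seed = 5)
  truth <- planted_truth(cohort_spec(12, "healthy", seed = 31))$ml_modules
  expect_equal(adjusted_rand(rec$community_id, truth), 1)

  labs <- default_marker_set()$label
  comm <- setNames(rec$community_id, labs)
  expect_equal(comm[["R_KNE"]], comm[["L_KNE"]])
  expect_equal(comm[["R_ANK"]], comm[["L_ANK"]])
})

test_that("negative-weight handling maps kinectome edges as configured", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- -0.8
  m[1, 3] <- m[3, 1] <- 0.4
  expect_equal(prepare_adjacency(m)[1, 2], 0.8)
  expect_equal(prepare_adjacency(m, "zero")[1, 2], 0)
  expect_equal(prepare_adjacency(m, "zero")[1, 3], 0.4)
  expect_equal(unname(diag(prepare_adjacency(m))), rep(0, 3))
})
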