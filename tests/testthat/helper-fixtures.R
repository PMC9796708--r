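# Shared fixtures and independent oracles used across test files.

# default analysis filter used on noisy synthetic trajectories
test_filter <- list(cutoff_hz = 4, order = 4)

# a tiny 3-marker set (one bilateral pair + one midline trunk marker)
tiny_marker_set <- function() {
  marker_set(
    labels = c("T10", "R_ANK", "L_ANK"),
    side = c("midline", "right", "left"),
    anatomical_group = c("trunk", "leg", "leg")
  )
}

# trial whose positions follow given per-axis functions of time
function_trial <- function(fun_ml, fun_ap = fun_ml, fun_v = fun_ml,
                           n_frames = 60, fs = 120, ms = tiny_marker_set(),
                           subject_id = "S1", session = "test") {
  tt <- (seq_len(n_frames) - 1) / fs
  pos <- array(0, c(n_frames, nrow(ms), 3))
  for (m in seq_len(nrow(ms))) {
    pos[, m, 1] <- fun_ml(tt, m)
    pos[, m, 2] <- fun_ap(tt, m)
    pos[, m, 3] <- fun_v(tt, m)
  }
  marker_trial(pos, ms, subject_id = subject_id, session = session,
               sampling_rate = fs)
}

# build test/retest kinectomes of one quantity/axis for a generated cohort
cohort_kinectomes <- function(cohort, quantity, axis, fp = test_filter) {
  pairing <- validate_session(cohort$trials, cohort$subjects)
  lapply(c(test = "test", retest = "retest"), function(sess) {
    lapply(pairing[[sess]], function(i) {
      build_kinectome(axis_series(cohort$trials[[i]], quantity, axis, fp))
    })
  })
}

cohort_edge_mats <- function(cohort, quantity, axis, fp = test_filter) {
  ks <- cohort_kinectomes(cohort, quantity, axis, fp)
  list(test = stack_edges(ks$test), retest = stack_edges(ks$retest))
}

# ---- independent oracles -------------------------------------------------

# brute-force double-loop evaluation of modularity Q
oracle_modularity_q <- function(A, comm) {
  A <- as.matrix(A)
  diag(A) <- 0
  n <- nrow(A)
  k <- rowSums(A)
  two_m <- sum(A)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (comm[i] == comm[j]) q <- q + A[i, j] - k[i] * k[j] / two_m
    }
  }
  q / two_m
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, max_used) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (v in 0:(max_used + 1)) {
      grow(c(labels, v), max(max_used, v))
    }
  }
  grow(integer(0), -1L)
  out
}

# exhaustive-search maximum modularity over all partitions
oracle_max_modularity <- function(A) {
  parts <- all_partitions(nrow(as.matrix(A)))
  max(vapply(parts, function(p) oracle_modularity_q(A, p), numeric(1)))
}

# one-way ANOVA ICC oracle via stats::aov, one edge at a time
oracle_icc_aov <- function(test_vals, retest_vals) {
  n <- length(test_vals)
  df <- data.frame(
    y = c(test_vals, retest_vals),
    subject = factor(rep(seq_len(n), 2))
  )
  tab <- summary(stats::aov(y ~ subject, data = df))[[1]]
  msa <- tab["subject", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  (msa - msw) / (msa + msw)
}

# random symmetric non-negative weighted adjacency
random_adjacency <- function(n, density = 0.6) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  w <- stats::runif(sum(up))
  w[stats::runif(sum(up)) > density] <- 0
  A[up] <- w
  A <- A + t(A)
  A
}

# adjusted Rand index between two labelings (independent implementation)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

two_triangle_graph <- function() {
  A <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  }
  A
}
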