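#' Per-edge test-retest intraclass correlation
#'
#' One-way random-effects ICC with subjects as clusters and the k = 2
#' sessions as observations: r = (MSA - MSW) / (MSA + (k - 1) * MSW),
#' where MSA is the among-subjects mean square and MSW the within-subject
#' mean square of that edge's values. Edges with zero total variance have
#' an undefined ICC, recorded as `NA` and ranked after all finite edges.
#'
#' @param test,retest `N x n_edges` matrices (same subject order).
#' @return List of class `icc_result`: `per_edge_icc`, `msa_per_edge`,
#'   `msw_per_edge`, `k`, `edge_order` (edge indices by descending ICC,
#'   ties broken by edge index, `NA` last).
#' @export
edge_icc <- function(test, retest) {
  test <- as.matrix(test)
  retest <- as.matrix(retest)
  if (!all(dim(test) == dim(retest))) stop_kin("test/retest dimensions differ")
  n <- nrow(test)
  if (n < 2) stop_kin("need at least 2 subjects")
  k <- 2L
  subj_mean <- (test + retest) / 2
  grand <- colMeans(rbind(test, retest))
  # one-way ANOVA decomposition per edge
  ssa <- k * colSums(sweep(subj_mean, 2, grand)^2)
  ssw <- colSums((test - subj_mean)^2) + colSums((retest - subj_mean)^2)
  msa <- ssa / (n - 1)
  msw <- ssw / (n * (k - 1))
  icc <- (msa - msw) / (msa + (k - 1) * msw)
  icc[msa + msw == 0] <- NA_real_ # zero total variance: undefined
  ord <- order(-icc, seq_along(icc), na.last = TRUE)
  structure(
    list(
      per_edge_icc = icc, msa_per_edge = msa, msw_per_edge = msw,
      k = k, edge_order = ord
    ),
    class = "icc_result"
  )
}

#' Identification-rate curve over nested edge subsets
#'
#' Starting from the first `start` edges of `edge_order` and adding one
#' edge per step up to the full set, computes the IR of the
#' identifiability matrix restricted to each subset.
#'
#' @param test,retest `N x n_edges` matrices.
#' @param edge_order permutation of `1:n_edges` (typically descending ICC
#'   from [edge_icc()]).
#' @param start smallest subset size (default 3).
#' @param match_direction passed to [fingerprint_scores()].
#' @return List of class `ir_curve`: `edge_counts`, `ir_values`,
#'   `edge_order`.
#' @export
ir_curve <- function(test, retest, edge_order, start = 3,
                     match_direction = "both") {
  n_edges <- ncol(as.matrix(test))
  if (!setequal(edge_order, seq_len(n_edges))) {
    stop_kin("edge_order must be a permutation of 1:", n_edges)
  }
  counts <- start:n_edges
  irs <- vapply(counts, function(cnt) {
    im <- identifiability_matrix(test, retest, edge_subset = edge_order[1:cnt])
    fingerprint_scores(im, match_direction = match_direction)$ir
  }, numeric(1))
  structure(
    list(edge_counts = counts, ir_values = irs, edge_order = edge_order),
    class = "ir_curve"
  )
}

#' Null IR curves from randomly ordered edges
#'
#' Builds `n_null` IR curves, each from a uniformly random edge ordering
#' (so each count uses a random subset of that size), and summarizes them
#' per count as mean and 95th/99th percentiles.
#'
#' @param test,retest `N x n_edges` matrices.
#' @param n_null number of random curves (default 100).
#' @param seed RNG seed.
#' @param start,match_direction see [ir_curve()].
#' @return List of class `ir_null_band`: `edge_counts`, `null_mean`,
#'   `null_p95`, `null_p99`, `null_curves` (n_null x counts matrix).
#' @export
null_ir_curves <- function(test, retest, n_null = 100, seed = NULL,
                           start = 3, match_direction = "both") {
  n_edges <- ncol(as.matrix(test))
  orders <- with_seed(seed, {
    lapply(seq_len(n_null), function(i) sample.int(n_edges))
  })
  curves <- t(vapply(orders, function(ord) {
    ir_curve(test, retest, ord, start = start,
             match_direction = match_direction)$ir_values
  }, numeric(n_edges - start + 1)))
  structure(
    list(
      edge_counts = start:n_edges,
      null_mean = colMeans(curves),
      null_p95 = apply(curves, 2, stats::quantile, probs = 0.95, names = FALSE),
      null_p99 = apply(curves, 2, stats::quantile, probs = 0.99, names = FALSE),
      null_curves = curves
    ),
    class = "ir_null_band"
  )
}

#' Edges of interest: smallest prefix exceeding an IR threshold
#'
#' Scans the curve for the smallest edge count whose IR exceeds
#' `ir_threshold` and returns that prefix of the edge order.
#'
#' @param curve an [ir_curve()].
#' @param ir_threshold IR level to exceed (default 0.99).
#' @return Integer vector of edge indices (empty, with a warning, if the
#'   threshold is never exceeded); attribute `n_edges` gives the count.
#' @export
edges_of_interest <- function(curve, ir_threshold = 0.99) {
  hit <- which(curve$ir_values > ir_threshold)
  if (!length(hit)) {
    warning("IR never exceeds ", ir_threshold, "; returning no edges")
    out <- integer(0)
    attr(out, "n_edges") <- 0L
    return(out)
  }
  cnt <- curve$edge_counts[hit[1]]
  out <- curve$edge_order[seq_len(cnt)]
  attr(out, "n_edges") <- cnt
  out
}

#' Markers hinging significantly many edges of interest
#'
#' Pools the given edge sets (one per kinectome parameter), counts how
#' often each marker is an endpoint, and compares against a null built
#' from equally sized uniformly random edge subsets. Markers whose count
#' exceeds the upper bound of the null 1-99% confidence interval are
#' flagged.
#'
#' @param edge_sets list of integer edge-index vectors (indices into the
#'   [edge_index()] order for `n_markers` nodes).
#' @param n_markers number of nodes (default 21).
#' @param n_null null draws (default 10000).
#' @param ci confidence level of the null interval (default 0.99: bounds
#'   at the 1st and 99th percentiles).
#' @param seed RNG seed.
#' @return List of class `node_occurrence`: `counts` (per marker),
#'   `null_upper`, `null_lower`, `significant` (logical per marker).
#' @export
node_occurrence_significance <- function(edge_sets, n_markers = 21,
                                         n_null = 10000, ci = 0.99,
                                         seed = NULL) {
  if (!length(edge_sets) || !sum(lengths(edge_sets))) {
    stop_kin("edge_sets must contain at least one edge")
  }
  idx <- edge_index(n_markers)
  count_nodes <- function(sets) {
    ends <- unlist(lapply(sets, function(s) c(idx$i[s], idx$j[s])))
    tabulate(ends, nbins = n_markers)
  }
  observed <- count_nodes(edge_sets)
  sizes <- lengths(edge_sets)
  n_edges <- nrow(idx)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_null), function(r) {
      count_nodes(lapply(sizes, function(sz) sample.int(n_edges, sz)))
    }, numeric(n_markers))
  })
  upper <- apply(null_counts, 1, stats::quantile, probs = ci, names = FALSE)
  lower <- apply(null_counts, 1, stats::quantile, probs = 1 - ci, names = FALSE)
  structure(
    list(
      counts = observed, null_upper = upper, null_lower = lower,
      significant = observed > upper
    ),
    class = "node_occurrence"
  )
}
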