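#' Build a kinectome from an axis series matrix
#'
#' The kinectome is the marker-by-marker matrix of Pearson correlation
#' coefficients between the per-marker time series (acceleration or jerk,
#' one axis). With 21 markers it is a symmetric 21 x 21 matrix with unit
#' diagonal, 420 off-diagonal entries of which 210 are unique.
#'
#' @param series an [axis_series()] or a `frames x markers` numeric matrix
#'   with marker-labelled columns.
#' @param subject_id,session,quantity,axis metadata; taken from `series`
#'   when it is an `axis_series`.
#' @return An object of class `kinectome`: list with `matrix`, `labels`,
#'   `subject_id`, `session`, `quantity`, `axis`.
#' @export
build_kinectome <- function(series, subject_id = NULL, session = NULL,
                            quantity = NULL, axis = NULL) {
  if (inherits(series, "axis_series")) {
    subject_id <- subject_id %||% series$subject_id
    session <- session %||% series$session
    quantity <- quantity %||% series$quantity
    axis <- axis %||% series$axis
    series <- series$values
  }
  series <- as.matrix(series)
  if (nrow(series) < 3) stop_kin("need at least 3 frames to correlate")
  sds <- apply(series, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(series)[sds == 0] %||% which(sds == 0)
    stop_kin(
      "zero-variance series for marker(s): ", paste(bad, collapse = ", ")
    )
  }
  m <- stats::cor(series)
  diag(m) <- 1
  structure(
    list(
      matrix = m, labels = colnames(series),
      subject_id = subject_id, session = session,
      quantity = quantity, axis = axis
    ),
    class = "kinectome"
  )
}

#' @export
print.kinectome <- function(x, ...) {
  cat(
    "<kinectome>", x$subject_id %||% "?", "(", x$session %||% "?", ")",
    x$quantity %||% "?", x$axis %||% "?", ":",
    nrow(x$matrix), "x", ncol(x$matrix), "\n"
  )
  invisible(x)
}

#' All six kinectomes of a trial
#'
#' 2 kinematic quantities (acceleration, jerk) x 3 axes (ML, AP, V).
#'
#' @param trial a [marker_trial()].
#' @param filter_policy see [axis_series()].
#' @param quantities,axes subsets to build (defaults: all).
#' @return Named list of [build_kinectome()] objects, names
#'   `"<quantity>.<axis>"`.
#' @export
trial_kinectomes <- function(trial, filter_policy = NULL,
                             quantities = c("acceleration", "jerk"),
                             axes = c("ML", "AP", "V")) {
  out <- list()
  for (q in quantities) {
    for (a in axes) {
      out[[paste(q, a, sep = ".")]] <-
        build_kinectome(axis_series(trial, q, a, filter_policy))
    }
  }
  out
}

#' Row-major upper-triangle index of an n x n matrix
#'
#' The canonical edge order used throughout the package:
#' (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n).
#'
#' @param n number of nodes.
#' @param labels optional node labels.
#' @return Data frame with columns `i`, `j` (and `marker_i`, `marker_j`
#'   when labels are given), one row per unique edge.
#' @export
edge_index <- function(n, labels = NULL) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  out <- data.frame(i = i, j = j)
  if (!is.null(labels)) {
    out$marker_i <- labels[i]
    out$marker_j <- labels[j]
  }
  out
}

#' Vectorize a kinectome into its unique edges
#'
#' Returns the row-major upper triangle (diagonal excluded): for 21
#' markers, 210 unique edges in the fixed [edge_index()] order.
#'
#' @param k a [build_kinectome()] object or a symmetric matrix.
#' @param tol asymmetry tolerance.
#' @return Numeric vector of length `n(n-1)/2` with attribute
#'   `edge_index` (the [edge_index()] data frame).
#' @export
vectorize <- function(k, tol = 1e-9) {
  m <- if (inherits(k, "kinectome")) k$matrix else as.matrix(k)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > tol) {
    stop_kin("matrix is not symmetric within tolerance ", tol)
  }
  idx <- edge_index(nrow(m), rownames(m) %||% (if (inherits(k, "kinectome")) k$labels))
  v <- m[cbind(idx$i, idx$j)]
  attr(v, "edge_index") <- idx
  v
}

#' Reassemble a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize()]; the diagonal is set to 1.
#'
#' @param v edge vector of length `n(n-1)/2`.
#' @param labels optional node labels.
#' @return Symmetric matrix with unit diagonal.
#' @export
unvectorize <- function(v, labels = NULL) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (n != round(n)) stop_kin("length ", length(v), " is not n(n-1)/2")
  n <- as.integer(n)
  idx <- edge_index(n)
  m <- diag(n)
  m[cbind(idx$i, idx$j)] <- v
  m[cbind(idx$j, idx$i)] <- v
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' Element-wise group statistics over kinectomes
#'
#' @param kinectomes list of [build_kinectome()] objects sharing labels,
#'   quantity and axis.
#' @param stat `"mean"` or `"sd"` (sample standard deviation).
#' @return A labelled square matrix.
#' @export
group_edge_stats <- function(kinectomes, stat = c("mean", "sd")) {
  stat <- match.arg(stat)
  if (length(kinectomes) < 2) stop_kin("need at least 2 kinectomes")
  ref <- kinectomes[[1]]
  for (k in kinectomes[-1]) {
    if (!identical(k$labels, ref$labels) ||
        !identical(k$quantity, ref$quantity) || !identical(k$axis, ref$axis)) {
      stop_kin("kinectomes mix labels, quantities or axes")
    }
  }
  arr <- simplify2array(lapply(kinectomes, function(k) k$matrix))
  out <- apply(arr, c(1, 2), if (stat == "mean") mean else stats::sd)
  dimnames(out) <- list(ref$labels, ref$labels)
  out
}

#' Permutation test for a two-group difference in means
#'
#' The observed statistic is the absolute difference of group means. The
#' null distribution is built by shuffling the pooled group labels
#' `n_perm` times and recomputing the statistic; the p-value uses the
#' add-one correction `p = (#{null >= observed} + 1) / (n_perm + 1)`.
#'
#' @param values_a,values_b per-subject scalars for the two groups.
#' @param n_perm number of label shuffles (default 10000).
#' @param seed RNG seed.
#' @return Object of class `perm_test`: list with `observed_stat`,
#'   `null_stats`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_compare <- function(values_a, values_b, n_perm = 10000, seed = NULL) {
  if (!length(values_a) || !length(values_b)) stop_kin("both groups must be non-empty")
  if (n_perm < 1) stop_kin("n_perm must be >= 1")
  observed <- abs(mean(values_a) - mean(values_b))
  pooled <- c(values_a, values_b)
  na <- length(values_a)
  n <- length(pooled)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, na)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    }, numeric(1))
  })
  structure(
    list(
      observed_stat = observed, null_stats = null_stats,
      p_value = (sum(null_stats >= observed) + 1) / (n_perm + 1),
      n_perm = n_perm, seed = seed
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(
    "<perm_test> observed =", format(x$observed_stat, digits = 4),
    " p =", format(x$p_value, digits = 4), " (", x$n_perm, "permutations )\n"
  )
  invisible(x)
}

#' Write a kinectome (or any labelled square matrix) as delimited text
#'
#' @param k a [build_kinectome()] object or matrix.
#' @param path output CSV path; a `<path>.json` sidecar stores metadata
#'   for kinectome objects.
#' @return `path`, invisibly.
#' @export
write_kinectome <- function(k, path) {
  m <- if (inherits(k, "kinectome")) k$matrix else as.matrix(k)
  if (inherits(k, "kinectome")) dimnames(m) <- list(k$labels, k$labels)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  if (inherits(k, "kinectome")) {
    meta <- k[c("subject_id", "session", "quantity", "axis")]
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}
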