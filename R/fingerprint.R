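#' Stack kinectome edge vectors into a subjects x edges matrix
#'
#' @param kinectomes list of [build_kinectome()] objects (one subject
#'   each, same labels/quantity/axis).
#' @return Numeric matrix, one row per subject (rownames = subject ids),
#'   columns in [edge_index()] order; attribute `edge_index`.
#' @export
stack_edges <- function(kinectomes) {
  vs <- lapply(kinectomes, vectorize)
  out <- do.call(rbind, vs)
  rownames(out) <- vapply(
    kinectomes, function(k) k$subject_id %||% NA_character_, character(1)
  )
  attr(out, "edge_index") <- attr(vs[[1]], "edge_index")
  out
}

#' Test-retest identifiability matrix
#'
#' Entry (i, j) is the Pearson correlation between subject i's test-session
#' edge vector and subject j's retest-session edge vector; the diagonal is
#' each subject's self-similarity across sessions. Generally not symmetric.
#'
#' @param test,retest `N x n_edges` matrices (rows = subjects, same
#'   subject order; see [stack_edges()]).
#' @param edge_subset optional integer index of edges to restrict to.
#' @return List of class `identifiability_matrix`: `matrix` (N x N),
#'   `subject_order`.
#' @export
identifiability_matrix <- function(test, retest, edge_subset = NULL) {
  test <- as.matrix(test)
  retest <- as.matrix(retest)
  if (!all(dim(test) == dim(retest))) stop_kin("test/retest dimensions differ")
  if (nrow(test) < 2) stop_kin("need at least 2 subjects")
  if (!is.null(edge_subset)) {
    if (any(edge_subset < 1 | edge_subset > ncol(test))) {
      stop_kin("edge_subset indices out of range")
    }
    test <- test[, edge_subset, drop = FALSE]
    retest <- retest[, edge_subset, drop = FALSE]
  }
  if (ncol(test) < 3) stop_kin("need at least 3 edges to correlate")
  sd_t <- apply(test, 1, stats::sd)
  sd_r <- apply(retest, 1, stats::sd)
  if (any(sd_t == 0) || any(sd_r == 0)) {
    stop_kin("zero-variance edge vector after restriction; cannot correlate")
  }
  im <- stats::cor(t(test), t(retest))
  dimnames(im) <- list(rownames(test), rownames(retest))
  structure(
    list(matrix = im, subject_order = rownames(test)),
    class = "identifiability_matrix"
  )
}

#' Fingerprint scores of an identifiability matrix
#'
#' I-self is the mean diagonal (within-subject test-retest similarity),
#' I-others the mean off-diagonal (between-subject similarity), I-diff
#' their difference (differential identifiability). The identification
#' rate (IR) is the fraction of subjects whose self-similarity exceeds
#' every one of their similarities with other subjects (both their row and
#' their column of the matrix; ties count as not identified).
#'
#' @param im an [identifiability_matrix()] or plain N x N matrix.
#' @param match_direction `"both"` (default: self must beat its row and
#'   column off-diagonals) or `"row"` (row only).
#' @return List of class `fingerprint_scores`: `iself_per_subject`,
#'   `iothers_per_subject`, `iself`, `iothers`, `idiff`, `ir` (in [0, 1];
#'   multiply by 100 for the percent scale used in reports).
#' @export
fingerprint_scores <- function(im, match_direction = c("both", "row")) {
  match_direction <- match.arg(match_direction)
  m <- if (inherits(im, "identifiability_matrix")) im$matrix else as.matrix(im)
  n <- nrow(m)
  if (n < 2 || ncol(m) != n) stop_kin("need a square matrix with N >= 2")
  iself_ps <- diag(m)
  iothers_ps <- numeric(n)
  identified <- logical(n)
  for (s in seq_len(n)) {
    row_off <- m[s, -s]
    col_off <- m[-s, s]
    others <- if (match_direction == "both") c(row_off, col_off) else row_off
    iothers_ps[s] <- mean(c(row_off, col_off))
    identified[s] <- iself_ps[s] > max(others)
  }
  iself <- mean(iself_ps)
  iothers <- mean(m[row(m) != col(m)])
  structure(
    list(
      iself_per_subject = iself_ps, iothers_per_subject = iothers_ps,
      iself = iself, iothers = iothers, idiff = iself - iothers,
      ir = mean(identified), identified = identified
    ),
    class = "fingerprint_scores"
  )
}

#' @export
print.fingerprint_scores <- function(x, ...) {
  cat(
    "<fingerprint_scores> I-self =", format(x$iself, digits = 3),
    " I-others =", format(x$iothers, digits = 3),
    " I-diff =", format(100 * x$idiff, digits = 3), "%",
    " IR =", format(100 * x$ir, digits = 3), "%\n"
  )
  invisible(x)
}

#' Compare per-subject fingerprint scores between two groups
#'
#' Permutation test (see [permutation_compare()]) on per-subject values of
#' I-self, I-others or I-diff. With 3 scores x 6 kinectome types the
#' Bonferroni family has 18 tests (cutoff 0.05/18).
#'
#' @param scores_a,scores_b per-subject score vectors.
#' @param n_perm,seed see [permutation_compare()].
#' @return A `perm_test` object.
#' @export
compare_fingerprints <- function(scores_a, scores_b, n_perm = 10000, seed = NULL) {
  permutation_compare(scores_a, scores_b, n_perm = n_perm, seed = seed)
}

#' Bonferroni-corrected significance cutoff
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_tests number of tests in the family (6 for quantity x axis
#'   kinectome comparisons, 18 for 3 fingerprint scores x 6 types).
#' @return `alpha / n_tests`.
#' @export
bonferroni_cutoff <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop_kin("n_tests must be >= 1")
  alpha / n_tests
}
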