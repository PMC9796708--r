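#' Newman modularity Q of a partition
#'
#' Q = (1/2m) * sum_ij [A_ij - k_i k_j / (2m)] * delta(c_i, c_j), where m
#' is the total edge weight, A the (symmetric, non-negative) adjacency,
#' k the weighted node degrees and c the community labels. Self-loops are
#' ignored (the diagonal is zeroed).
#'
#' @param adjacency symmetric non-negative weight matrix.
#' @param partition integer community labels, one per node (a `partition`
#'   object or a plain vector).
#' @return Q in `[-1, 1]`.
#' @export
modularity_q <- function(adjacency, partition) {
  A <- as_adjacency(adjacency)
  comm <- partition_labels(partition, n = nrow(A))
  k <- rowSums(A)
  two_m <- sum(A)
  if (two_m == 0) stop_kin("adjacency has zero total weight")
  same <- outer(comm, comm, "==")
  sum((A - outer(k, k) / two_m) * same) / two_m
}

as_adjacency <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 1e-9) {
    stop_kin("adjacency must be a symmetric square matrix")
  }
  diag(A) <- 0
  if (any(A < 0)) {
    stop_kin(
      "adjacency has negative weights; map them first ",
      "(see prepare_adjacency)"
    )
  }
  A
}

partition_labels <- function(partition, n = NULL) {
  comm <- if (inherits(partition, "partition")) partition$community_id else partition
  comm <- as.integer(comm)
  if (!is.null(n) && length(comm) != n) {
    stop_kin("partition has ", length(comm), " labels for ", n, " nodes")
  }
  comm
}

new_partition <- function(community_id, q_value, labels = NULL) {
  # contiguous ids from 0 in order of first appearance
  community_id <- match(community_id, unique(community_id)) - 1L
  structure(
    list(community_id = community_id, q_value = q_value, labels = labels),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat(
    "<partition>", length(unique(x$community_id)), "communities over",
    length(x$community_id), "nodes, Q =", format(x$q_value, digits = 4), "\n"
  )
  invisible(x)
}

#' Map kinectome weights to non-negative adjacency
#'
#' Louvain modularity assumes non-negative weights while correlations can
#' be negative. `"abs"` (default) takes absolute values, preserving the
#' strength of anti-phase coupling; `"zero"` discards negative edges.
#'
#' @param m square weight matrix or [build_kinectome()] object.
#' @param negatives `"abs"` or `"zero"`.
#' @return Non-negative symmetric matrix with zero diagonal.
#' @export
prepare_adjacency <- function(m, negatives = c("abs", "zero")) {
  negatives <- match.arg(negatives)
  A <- if (inherits(m, "kinectome")) m$matrix else as.matrix(m)
  A <- if (negatives == "abs") abs(A) else pmax(A, 0)
  diag(A) <- 0
  A
}

#' Louvain community detection
#'
#' Thin seeded wrapper around [igraph::cluster_louvain()]; returns the
#' partition together with its modularity Q on the given graph.
#'
#' @param adjacency symmetric non-negative weight matrix.
#' @param seed RNG seed (Louvain visits nodes in random order).
#' @param resolution resolution parameter (1 = plain modularity).
#' @return A `partition` object: `community_id` (0-based, contiguous),
#'   `q_value`, `labels`.
#' @export
louvain <- function(adjacency, seed = NULL, resolution = 1) {
  A <- as_adjacency(adjacency)
  g <- igraph::graph_from_adjacency_matrix(
    A, mode = "undirected", weighted = TRUE, diag = FALSE
  )
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  comm <- as.integer(igraph::membership(cl))
  new_partition(comm, modularity_q(A, comm), labels = rownames(A))
}

coassignment <- function(partitions) {
  n <- length(partition_labels(partitions[[1]]))
  D <- matrix(0, n, n)
  for (p in partitions) {
    comm <- partition_labels(p, n = n)
    D <- D + outer(comm, comm, "==")
  }
  D / length(partitions)
}

#' Consensus clustering over repeated Louvain runs
#'
#' Runs Louvain `n_iter` times with varied sub-seeds, forms the
#' co-assignment matrix, zeroes entries below the chance level expected
#' from label-permuted partitions, re-clusters, and iterates until the
#' co-assignment matrix is binary. The fixed-point partition is returned
#' with its Q evaluated on the original adjacency.
#'
#' @param adjacency symmetric non-negative weight matrix.
#' @param n_iter Louvain runs per round (default 100).
#' @param seed RNG seed.
#' @param resolution passed to [louvain()].
#' @param max_rounds outer-iteration cap; exceeded means no convergence.
#' @return A `partition` object.
#' @export
consensus_cluster <- function(adjacency, n_iter = 100, seed = NULL,
                              resolution = 1, max_rounds = 50) {
  A <- as_adjacency(adjacency)
  n <- nrow(A)
  current <- A
  for (round in seq_len(max_rounds)) {
    parts <- lapply(seq_len(n_iter), function(i) {
      louvain(current, seed = spawn_seed(seed %||% 0L, round * 1000L + i),
              resolution = resolution)
    })
    D <- coassignment(parts)
    offdiag <- D[lower.tri(D)]
    if (all(offdiag %in% c(0, 1))) {
      final <- louvain(D, seed = spawn_seed(seed %||% 0L, round * 1000L),
                       resolution = resolution)
      return(new_partition(
        final$community_id, modularity_q(A, final$community_id),
        labels = rownames(A) %||% final$labels
      ))
    }
    # null co-assignment level from label-permuted partitions
    null_mean <- with_seed(spawn_seed(seed %||% 0L, round), {
      mean(vapply(parts, function(p) {
        comm <- sample(partition_labels(p, n = n))
        mean(outer(comm, comm, "==")[lower.tri(D)])
      }, numeric(1)))
    })
    D[D < null_mean] <- 0
    diag(D) <- 1
    current <- D
  }
  stop_kin("consensus clustering did not converge after ", max_rounds, " rounds")
}

#' Allegiance matrix of a set of partitions
#'
#' Entry (i, j) is the fraction of partitions in which nodes i and j share
#' a community — the probability of two markers being clustered together
#' across subjects (and kinematic quantities).
#'
#' @param partitions list of `partition` objects (or label vectors) over
#'   the same node set.
#' @return List of class `allegiance`: `matrix` (symmetric, unit
#'   diagonal), `n_partitions`.
#' @export
allegiance <- function(partitions) {
  if (!length(partitions)) stop_kin("need at least one partition")
  n <- length(partition_labels(partitions[[1]]))
  for (p in partitions) partition_labels(p, n = n) # length check
  D <- coassignment(partitions)
  labs <- if (inherits(partitions[[1]], "partition")) partitions[[1]]$labels
  if (!is.null(labs)) dimnames(D) <- list(labs, labs)
  structure(
    list(matrix = D, n_partitions = length(partitions)),
    class = "allegiance"
  )
}

#' Group-level communities from an allegiance matrix
#'
#' Applies [consensus_cluster()] to the allegiance matrix, yielding the
#' group-level modules (sets of body parts that move as one functional
#' unit across the cohort).
#'
#' @param alleg an [allegiance()] object or probability matrix.
#' @param seed RNG seed.
#' @param n_iter,resolution passed to [consensus_cluster()].
#' @return A `partition` object.
#' @export
group_communities <- function(alleg, seed = NULL, n_iter = 100, resolution = 1) {
  m <- if (inherits(alleg, "allegiance")) alleg$matrix else as.matrix(alleg)
  consensus_cluster(m, n_iter = n_iter, seed = seed, resolution = resolution)
}
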