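# Generalized Louvain modularity maximization for an arbitrary (possibly
# signed) symmetric modularity matrix B, plus consensus clustering over an
# ensemble of partitions. Q = sum_{i != j, sigma_i == sigma_j} B_ij: the sum
# of within-community elements, diagonal excluded (diagonal terms are
# partition-independent).

#' Modularity of a partition under a modularity matrix
#'
#' @param B symmetric modularity matrix (observed minus expected weights)
#' @param labels integer community assignment, one per item
#' @return scalar Q = sum of within-community off-diagonal elements of B
#' @export
partition_modularity <- function(B, labels) {
  stopifnot(nrow(B) == length(labels))
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE
  sum(B[same])
}

#' Per-community modularity contributions
#'
#' q_c = sum_{i,j in c, i != j} B_ij, so that sum_c q_c equals
#' [partition_modularity()] exactly.
#'
#' @param B symmetric modularity matrix
#' @param labels community assignment (1-based contiguous)
#' @return named numeric vector of q_c, one per community id
#' @export
community_contributions <- function(B, labels) {
  Bd <- B
  diag(Bd) <- 0
  agg <- rowsum(t(rowsum(Bd, labels)), labels)
  q <- diag(as.matrix(agg))
  names(q) <- rownames(agg)
  q
}

# One Louvain pass + aggregation levels on modularity matrix M.
# Maintains G[i, c] = sum_{j in c, j != i} M_ij incrementally so each local
# move is O(n). Returns 1-based contiguous labels for the rows of M.
louvain_once <- function(B) {
  n <- nrow(B)
  M <- B
  diag(M) <- 0
  membership <- seq_len(n)
  repeat {
    m <- nrow(M)
    lab <- seq_len(m)
    G <- M # with singleton communities, G[i, c] = M[i, c]
    moved_any <- FALSE
    repeat {
      moved <- FALSE
      for (i in sample.int(m)) {
        cur <- lab[i]
        gains <- G[i, ] - G[i, cur]
        best <- which.max(gains)
        if (best != cur && gains[best] > 1e-12) {
          lab[i] <- best
          G[, cur] <- G[, cur] - M[, i]
          G[, best] <- G[, best] + M[, i]
          moved <- TRUE
          moved_any <- TRUE
        }
      }
      if (!moved) break
    }
    lab <- canonical_labels(lab)
    membership <- lab[membership]
    k <- max(lab)
    if (!moved_any || k == m) break
    # aggregate: super-node matrix; within-community weight moves to diagonal
    # (a fixed self-loop that no longer influences local gains)
    M2 <- rowsum(t(rowsum(M, lab)), lab)
    M <- as.matrix(M2)
    diag(M) <- 0 # self-loops are partition-invariant from here on
  }
  membership
}

#' Maximize modularity with repeated Louvain runs
#'
#' Runs a generalized Louvain algorithm `n_iter` times (random node sweep
#' orders) on the supplied modularity matrix, which may be signed. Each run's
#' partition is floored at the one-community partition: if grouping everything
#' together scores higher than the local optimum found, the one-community
#' partition is returned for that run, so Q(run) >= Q(single community)
#' always.
#'
#' @param B symmetric finite modularity matrix
#' @param n_iter number of independent runs
#' @param seed integer seed (the run ensemble is fully reproducible)
#' @return list of class `partition_ensemble`; each element is a `partition`:
#'   `assignment` (1-based contiguous ids), `Q`, `B_description`
#' @export
maximize_modularity <- function(B, n_iter = 100L, seed = 1L) {
  if (!is.matrix(B) || nrow(B) != ncol(B)) stop("B must be square")
  if (!all(is.finite(B))) stop("B must be finite")
  if (max(abs(B - t(B))) > 1e-8) stop("B must be symmetric")
  desc <- attr(B, "B_description") %||% "user-supplied modularity matrix"
  one_q <- partition_modularity(B, rep(1L, nrow(B)))
  with_seed(seed, {
    runs <- lapply(seq_len(n_iter), function(r) {
      lab <- louvain_once(B)
      q <- partition_modularity(B, lab)
      # floor at the trivial partition; on an exact tie (e.g. B == 0) prefer
      # the coarser one-community solution: no evidence for structure
      if (q < one_q + 1e-12) {
        lab <- rep(1L, nrow(B))
        q <- one_q
      }
      structure(list(assignment = lab, Q = q, B_description = desc),
                class = "partition")
    })
    structure(runs, class = "partition_ensemble")
  })
}

# Coassignment fraction matrix of an ensemble of label vectors (columns of L).
coassignment_matrix <- function(L) {
  n <- nrow(L)
  A <- matrix(0, n, n)
  for (r in seq_len(ncol(L))) A <- A + outer(L[, r], L[, r], "==")
  A / ncol(L)
}

# Expected coassignment under random size-preserving label permutation:
# for each partition with community sizes s_k, any two distinct items land in
# the same community with probability sum s_k (s_k - 1) / (n (n - 1)).
expected_coassignment <- function(L) {
  n <- nrow(L)
  e <- vapply(seq_len(ncol(L)), function(r) {
    s <- tabulate(L[, r])
    sum(s * (s - 1)) / (n * (n - 1))
  }, numeric(1))
  mean(e)
}

#' Consensus partition of an ensemble
#'
#' Builds the coassignment fraction matrix of the ensemble, subtracts its
#' chance expectation (size-preserving label permutation), and re-optimizes
#' modularity on that consensus matrix; the procedure repeats on the new
#' ensemble until every run agrees up to relabeling, or an iteration cap is
#' hit (the result is then flagged `converged = FALSE` with a warning, never
#' an uncaught failure).
#'
#' @param ensemble a `partition_ensemble` (>= 2 partitions of the same items)
#' @param seed integer seed
#' @param n_iter Louvain runs per consensus round (default: ensemble size)
#' @param max_rounds cap on consensus rounds
#' @return a `partition` with extra fields `converged` and `rounds`
#' @export
consensus_partition <- function(ensemble, seed = 1L, n_iter = NULL,
                                max_rounds = 50L) {
  stopifnot(inherits(ensemble, "partition_ensemble"))
  if (length(ensemble) < 2) stop("need >= 2 partitions for a consensus")
  L <- vapply(ensemble, function(p) as.integer(p$assignment),
              integer(length(ensemble[[1]]$assignment)))
  n_iter <- n_iter %||% length(ensemble)
  rounds <- 0L
  converged <- FALSE
  repeat {
    # already unanimous (up to relabeling)?
    canon <- apply(L, 2, canonical_labels)
    if (all(canon == canon[, 1])) {
      converged <- TRUE
      L <- canon
      break
    }
    if (rounds >= max_rounds) break
    rounds <- rounds + 1L
    Bc <- coassignment_matrix(L) - expected_coassignment(L)
    attr(Bc, "B_description") <- "consensus: coassignment - expected coassignment"
    ens <- maximize_modularity(Bc, n_iter = n_iter,
                               seed = derive_seed(seed, paste0("consensus", rounds)))
    L <- vapply(ens, function(p) p$assignment, integer(nrow(Bc)))
  }
  if (!converged) {
    warning("consensus did not converge within ", max_rounds,
            " rounds; returning the modal partition, flagged non-convergent")
    canon <- apply(L, 2, canonical_labels)
    keys <- apply(canon, 2, paste, collapse = ",")
    L <- canon[, which.max(table(keys)[keys]), drop = FALSE]
  }
  lab <- canonical_labels(L[, 1])
  structure(list(assignment = lab, Q = NA_real_,
                 B_description = "consensus partition",
                 converged = converged, rounds = rounds),
            class = "partition")
}
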