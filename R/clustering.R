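# Recursive consensus clustering of event co-fluctuation patterns.
#
# Level 1 clusters the concordance matrix C against a uniform expectation
# <C> = mean of C's upper triangle. Each consensus community is tested
# against a size-preserving label-permutation null for its modularity
# contribution q_c; significant communities of size >= 3 are recursed on
# their induced sub-matrix (with <C> recomputed within the child). Pruning
# stops insignificant branches, yielding a hierarchy of statistically
# supported event clusters.

# q_c permutation null: permute the label vector n_perm times and collect
# each community's contribution under the permuted labels.
community_pvalues <- function(B, labels, n_perm, seed) {
  q_obs <- community_contributions(B, labels)
  k <- length(q_obs)
  Bd <- B
  diag(Bd) <- 0
  with_seed(seed, {
    exceed <- numeric(k)
    for (p in seq_len(n_perm)) {
      pl <- labels[sample.int(length(labels))]
      qp <- diag(as.matrix(rowsum(t(rowsum(Bd, pl)), pl)))
      exceed <- exceed + (qp >= q_obs)
    }
    (1 + exceed) / (1 + n_perm)
  })
}

modularity_matrix_uniform <- function(C) {
  B <- C - mean(upper_vec(unclass(C)))
  attr(B, "B_description") <- "C - mean(upper triangle of C)"
  B
}

#' Hierarchically cluster event patterns from their concordance matrix
#'
#' @param cm M x M [concordance_matrix()]
#' @param n_iter Louvain runs per consensus (default 1000)
#' @param n_perm label permutations for the pruning test (default 1000)
#' @param alpha one-sided significance level for q_c pruning (default 0.05)
#' @param seed integer seed
#' @param min_size smallest community eligible for further subdivision
#' @return object of class `hierarchical_partition`:
#'   \describe{
#'     \item{levels}{list of integer assignments; `levels[[1]]` is the single
#'       root community, `levels[[2]]` the first consensus partition, and each
#'       deeper level refines only the significant communities of its parent}
#'     \item{nodes}{data.frame describing every community node: `id`, `level`,
#'       `parent`, `size`, `q_local` (contribution on its parent's modularity
#'       matrix), `p_value`, `significant`, `subdivided`}
#'     \item{parent_map}{per level >= 2, integer vector mapping each
#'       community id to its parent community id on the previous level}
#'     \item{q_contributions}{per level, q_c of each community on the global
#'       modularity matrix, so `sum(q_contributions[[l]])` equals the level's
#'       total modularity exactly}
#'     \item{Q_levels}{total modularity of each level's assignment on the
#'       global matrix}
#'   }
#' @export
hierarchical_cluster_events <- function(cm, n_iter = 1000L, n_perm = 1000L,
                                        alpha = 0.05, seed = 1L,
                                        min_size = 3L) {
  stopifnot(inherits(cm, "concordance_matrix"))
  C <- unclass(cm)
  m <- nrow(C)
  nodes <- list()
  node_id <- 0L
  new_node <- function(level, parent, members, q_local, p_value, significant) {
    node_id <<- node_id + 1L
    nodes[[node_id]] <<- list(id = node_id, level = level, parent = parent,
                              members = members, q_local = q_local,
                              p_value = p_value, significant = significant,
                              subdivided = FALSE)
    node_id
  }
  counter <- 0L
  next_seed <- function() {
    # content-independent counter so clustering is invariant (up to
    # relabeling) to input pattern order
    counter <<- counter + 1L
    derive_seed(seed, paste0("hclust", counter))
  }
  root <- new_node(1L, NA_integer_, seq_len(m), NA_real_, NA_real_, TRUE)

  recurse <- function(parent_id) {
    members <- nodes[[parent_id]]$members
    Csub <- C[members, members, drop = FALSE]
    B <- modularity_matrix_uniform(Csub)
    ens <- maximize_modularity(B, n_iter = n_iter, seed = next_seed())
    cons <- consensus_partition(ens, seed = next_seed(), n_iter = n_iter)
    if (!cons$converged) {
      stop("consensus failed to converge while subdividing community path ",
           paste(community_path(nodes, parent_id), collapse = " > "))
    }
    lab <- cons$assignment
    k <- max(lab)
    if (k < 2) return(invisible(NULL)) # no subdivision found
    q <- community_contributions(B, lab)
    p <- community_pvalues(B, lab, n_perm, next_seed())
    if (!any(p < alpha)) {
      # every candidate community is consistent with the permutation null:
      # the whole subdivision is discarded and the parent stays a leaf
      return(invisible(NULL))
    }
    nodes[[parent_id]]$subdivided <<- TRUE
    for (c_id in seq_len(k)) {
      child_members <- members[lab == c_id]
      sig <- p[c_id] < alpha
      child <- new_node(nodes[[parent_id]]$level + 1L, parent_id,
                        child_members, unname(q[c_id]), p[c_id], sig)
      if (sig && length(child_members) >= min_size) recurse(child)
    }
    invisible(NULL)
  }
  recurse(root)
  build_hierarchy(nodes, C, m)
}

community_path <- function(nodes, id) {
  path <- integer(0)
  while (!is.na(id)) {
    path <- c(id, path)
    id <- nodes[[id]]$parent
  }
  path
}

# Assemble flat per-level assignments from the pruned tree. At level L every
# item belongs to the deepest ancestor node with level <= L; ids are
# relabeled contiguous within each level.
build_hierarchy <- function(nodes, C, m) {
  depth <- max(vapply(nodes, `[[`, integer(1), "level"))
  B_global <- modularity_matrix_uniform(C)
  levels_ <- list()
  parent_map <- list()
  q_contributions <- list()
  Q_levels <- numeric(depth)
  prev_node_of_comm <- NULL
  for (L in seq_len(depth)) {
    assign_node <- integer(m) # node id covering each item at this level
    for (nd in nodes) {
      if (nd$level <= L && !(nd$subdivided && nd$level < L)) {
        assign_node[nd$members] <- nd$id
      }
    }
    node_ids <- unique(assign_node)
    lab <- match(assign_node, node_ids)
    levels_[[L]] <- lab
    q_contributions[[L]] <- community_contributions(B_global, lab)
    Q_levels[L] <- partition_modularity(B_global, lab)
    if (L > 1) {
      parent_map[[L]] <- vapply(node_ids, function(id) {
        p <- nodes[[id]]$parent
        # carried-forward nodes are their own parent on the previous level
        pid <- if (is.na(p) || nodes[[id]]$level < L) id else p
        match(pid, prev_node_of_comm)
      }, integer(1))
    }
    prev_node_of_comm <- node_ids
  }
  node_df <- do.call(rbind, lapply(nodes, function(nd) {
    data.frame(id = nd$id, level = nd$level, parent = nd$parent,
               size = length(nd$members), q_local = nd$q_local,
               p_value = nd$p_value, significant = nd$significant,
               subdivided = nd$subdivided)
  }))
  structure(list(levels = levels_, nodes = node_df, node_members =
                   lapply(nodes, `[[`, "members"), parent_map = parent_map,
                 q_contributions = q_contributions, Q_levels = Q_levels,
                 depth = depth),
            class = "hierarchical_partition")
}

#' @export
print.hierarchical_partition <- function(x, ...) {
  cat(sprintf("<hierarchical_partition> depth %d\n", x$depth))
  for (L in seq_len(x$depth)) {
    cat(sprintf("  level %d: %d communities, Q = %.4f\n", L,
                max(x$levels[[L]]), x$Q_levels[L]))
  }
  invisible(x)
}

#' Cluster centroids of a pattern ensemble
#'
#' Elementwise mean pattern per cluster, with member counts and fractions.
#'
#' @param ensemble a [pattern_ensemble()]
#' @param assignment integer cluster label per pattern (1-based contiguous)
#' @return list of class `centroid_set`: `centroids` (list of
#'   [cofluct_pattern()]), `member_count`, `member_fraction`
#' @export
compute_centroids <- function(ensemble, assignment) {
  stopifnot(inherits(ensemble, "pattern_ensemble"),
            length(assignment) == ensemble$M)
  k <- max(assignment)
  centroids <- vector("list", k)
  counts <- tabulate(assignment, k)
  for (c_id in seq_len(k)) {
    members <- which(assignment == c_id)
    acc <- Reduce(`+`, lapply(ensemble$patterns[members], unclass))
    centroids[[c_id]] <- cofluct_pattern(acc / length(members),
                                         source = "centroid")
  }
  structure(list(centroids = centroids, member_count = counts,
                 member_fraction = counts / ensemble$M),
            class = "centroid_set")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b integer label vectors of equal length
#' @return scalar ARI
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
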