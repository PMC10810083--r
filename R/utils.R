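# Internal helpers shared across modules: seeded evaluation, the canonical
# row-major upper-triangle edge ordering, and label canonicalization.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions never disturb
#' the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

#' Derive a stage seed from a base seed and a stage name
#'
#' Deterministic, collision-unlikely, and always in [1, 2^31 - 2] so it is a
#' valid R integer seed. Used by the pipeline driver so one configured seed
#' reproduces every stage independently.
#' @param seed integer base seed
#' @param stage character stage name
#' @return integer seed
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(stage)) {
    # Horner's scheme mod m; multiplier small enough for exact double arithmetic
    h <- (h * 131 + k) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Row-major upper-triangle edge index
#'
#' All E = N(N-1)/2 node pairs (i, j) with i < j in row-major order:
#' (1,2), (1,3), ..., (1,N), (2,3), ... This single ordering is used for edge
#' time series rows, vectorized patterns, and files, so representations are
#' bit-exact interchangeable.
#' @param n_nodes number of nodes
#' @return two-column integer matrix with columns `i`, `j` (1-based)
#' @export
edge_index <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(a) (a + 1L):n_nodes),
              use.names = FALSE)
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Vectorize the upper triangle of a square matrix in row-major edge order
#' @param m square matrix
#' @return numeric vector of length N(N-1)/2
#' @export
upper_vec <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[edge_index(nrow(m))]
}

#' Rebuild a symmetric zero-diagonal matrix from its row-major upper triangle
#' @param v vector of length N(N-1)/2
#' @param n_nodes N
#' @return N x N symmetric matrix with zero diagonal
#' @export
unvec_sym <- function(v, n_nodes) {
  idx <- edge_index(n_nodes)
  stopifnot(length(v) == nrow(idx))
  m <- matrix(0, n_nodes, n_nodes)
  m[idx] <- v
  m[idx[, c(2, 1)]] <- v
  m
}

# Relabel community ids to contiguous 1..K in order of first appearance.
canonical_labels <- function(labels) {
  match(labels, unique(labels))
}

# Partition equality up to relabeling.
same_partition <- function(a, b) {
  identical(canonical_labels(a), canonical_labels(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
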