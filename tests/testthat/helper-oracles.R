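# Independent brute-force oracles. These deliberately use naive loops and
# textbook formulas, never the package's vectorized paths.

oracle_rms_frame <- function(z_frame) {
  n <- length(z_frame)
  acc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) acc <- acc + (z_frame[i] * z_frame[j])^2
  }
  sqrt(2 * acc / (n * (n - 1)))
}

# Q = sum_ij B_ij delta(sigma_i, sigma_j), literal double loop, i != j
oracle_modularity <- function(B, labels) {
  n <- nrow(B)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && labels[i] == labels[j]) q <- q + B[i, j]
    }
  }
  q
}

# Q_induced via literal double loops over ordered pairs within c+ and c-,
# with B^sc built from the full connectome's strengths
oracle_induced <- function(W, plus, minus) {
  n <- nrow(W)
  k_in <- sapply(seq_len(n), function(i) sum(W[i, ]))
  k_out <- sapply(seq_len(n), function(j) sum(W[, j]))
  two_m <- sum(k_in)
  bsc <- function(i, j) W[i, j] - k_in[i] * k_out[j] / two_m
  q <- 0
  for (i in plus) for (j in plus) if (i != j) q <- q + bsc(i, j)
  for (i in minus) for (j in minus) if (i != j) q <- q + bsc(i, j)
  q
}

oracle_concordance <- function(x, y) {
  2 * cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)
}

# All set partitions of n items as restricted-growth strings.
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, max_used) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (g in seq_len(max_used + 1L)) {
      rec(c(prefix, g), max(max_used, g))
    }
  }
  rec(integer(0), 0L)
  out
}

# Exact enumeration of all disjoint (plus, minus) assignments of the given
# sizes on n nodes; returns every Q_induced value.
enumerate_induced_null <- function(W, n_plus, n_minus) {
  n <- nrow(W)
  out <- numeric(0)
  for (plus in asplit(combn(n, n_plus), 2)) {
    rest <- setdiff(seq_len(n), plus)
    for (minus in asplit(combn(rest, n_minus), 2)) {
      out <- c(out, oracle_induced(W, plus, minus))
    }
  }
  out
}

# Small fast synthetic config for unit tests.
quick_config <- function(seed = 7L, ...) {
  synth_config(n_frames = 400L, n_events = 8L, seed = seed, ...)
}

# Three well-separated planted activation modes on 40 nodes.
planted_modes_3 <- function() {
  list(c(rep(1, 20), rep(-1, 20)),
       c(rep(1, 10), rep(-1, 10), rep(1, 10), rep(-1, 10)),
       rep(c(1, -1), 20))
}

# Nested design: two orthogonal super-modes, each with two subtle variants.
nested_modes <- function(delta = 0.3) {
  mA <- c(rep(1, 20), rep(-1, 20))
  mB <- c(rep(1, 10), rep(-1, 10), rep(1, 10), rep(-1, 10))
  bump <- function(v, idx) { v[idx] <- v[idx] * (1 + delta); v }
  list(bump(mA, 1:10), bump(mA, 11:20), bump(mB, 1:10), bump(mB, 21:30))
}

random_connectome <- function(n, seed) {
  set.seed(seed)
  w <- matrix(runif(n * n), n, n)
  diag(w) <- 0
  structural_connectome(w)
}
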