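test_that("Lin's concordance matches the direct formula and its identities", {
  # direct-formula oracle: sample moments give 2*2 / (1 + 4 + 4) = 4/9
  expect_equal(lin_concordance(c(1, 2, 3), c(2, 4, 6)), 4 / 9)
  expect_equal(lin_concordance(c(1, 2, 3), c(2, 4, 6)),
               oracle_concordance(c(1, 2, 3), c(2, 4, 6)))

  set.seed(61)
  x <- rnorm(50)
  expect_equal(lin_concordance(x, x), 1)

  # equal means and variances -> concordance == Pearson r
  y <- rnorm(50)
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(x)
  expect_equal(lin_concordance(x, y), cor(x, y), tolerance = 1e-12)

  # |C| <= |r| over random unconstrained pairs
  for (k in 1:50) {
    a <- rnorm(30, mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
    b <- rnorm(30, mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
    expect_lte(abs(lin_concordance(a, b)), abs(cor(a, b)) + 1e-12)
  }
  expect_error(lin_concordance(rep(1, 5), rep(1, 5)), "undefined")
})

test_that("concordance matrix matches a pairwise loop oracle", {
  lib <- generate_event_pattern_library(4, planted_modes_3(), noise_sd = 0.5,
                                        seed = 8)
  cm <- concordance_matrix(lib$ensemble)
  m <- lib$ensemble$M
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      expect_equal(cm[a, b],
                   lin_concordance(upper_vec(unclass(lib$ensemble$patterns[[a]])),
                                   upper_vec(unclass(lib$ensemble$patterns[[b]]))),
                   tolerance = 1e-12)
    }
  }
  expect_equal(unname(diag(cm)), rep(1, m))
  # pattern and its negation are anticoncordant
  p <- lib$ensemble$patterns[[1]]
  neg <- cofluct_pattern(-unclass(p))
  cm2 <- concordance_matrix(pattern_ensemble(list(p, neg)))
  expect_lt(cm2[1, 2], 0)
  # duplicates give an all-ones matrix
  cm3 <- concordance_matrix(pattern_ensemble(list(p, p, p)))
  expect_equal(max(abs(unclass(cm3) - 1)), 0)
})

test_that("modularity maximization finds the unambiguous optimum and beats the trivial partition", {
  blocks <- rep(1:2, each = 4)
  B <- ifelse(outer(blocks, blocks, "=="), 1, -1)
  diag(B) <- 0
  ens <- maximize_modularity(B, n_iter = 10, seed = 2)
  for (p in ens) {
    expect_equal(max(p$assignment), 2L)
    expect_gte(p$Q, partition_modularity(B, rep(1L, 8)))
    expect_equal(adjusted_rand_index(p$assignment, blocks), 1)
  }
  expect_error(maximize_modularity(matrix(1:9, 3), 5), "symmetric")
})

test_that("Louvain attains the exhaustive maximum on 8-item instances", {
  parts <- enumerate_partitions(8)
  for (seed in 1:5) {
    set.seed(seed)
    blocks <- sample(1:3, 8, replace = TRUE)
    B <- ifelse(outer(blocks, blocks, "=="), 1, -0.8) +
      matrix(rnorm(64, sd = 0.3), 8, 8)
    B <- (B + t(B)) / 2
    diag(B) <- 0
    best <- max(vapply(parts, function(lab) oracle_modularity(B, lab),
                       numeric(1)))
    ens <- maximize_modularity(B, n_iter = 20, seed = seed)
    expect_equal(max(vapply(ens, `[[`, numeric(1), "Q")), best,
                 tolerance = 1e-10)
  }
})

test_that("Q and q_c agree with the double-loop oracle and decompose exactly", {
  set.seed(62)
  B <- matrix(rnorm(100), 10, 10)
  B <- (B + t(B)) / 2
  lab <- sample(1:3, 10, replace = TRUE)
  lab <- cofluct:::canonical_labels(lab)
  expect_equal(partition_modularity(B, lab), oracle_modularity(B, lab),
               tolerance = 1e-12)
  expect_equal(sum(community_contributions(B, lab)),
               partition_modularity(B, lab), tolerance = 1e-10)
})

test_that("consensus returns fixed points, planted partitions, and labels degeneracy", {
  blocks <- rep(1:2, each = 10)
  make_part <- function(lab) {
    structure(list(assignment = lab, Q = 0, B_description = "fixture"),
              class = "partition")
  }
  # identical inputs -> unchanged in one pass
  ens <- structure(lapply(1:5, function(i) make_part(blocks)),
                   class = "partition_ensemble")
  cons <- consensus_partition(ens, seed = 1)
  expect_true(cons$converged)
  expect_equal(cons$rounds, 0L)
  expect_true(cofluct:::same_partition(cons$assignment, blocks))

  # planted partitions with 10% label noise -> planted consensus
  set.seed(63)
  noisy <- lapply(1:20, function(i) {
    lab <- blocks
    flip <- sample(20, 2)
    lab[flip] <- 3 - lab[flip]
    make_part(lab)
  })
  cons2 <- consensus_partition(structure(noisy, class = "partition_ensemble"),
                               seed = 2, n_iter = 50)
  expect_true(cons2$converged)
  expect_equal(adjusted_rand_index(cons2$assignment, blocks), 1)

  # unrelated random partitions: never crashes, outcome labeled
  set.seed(64)
  rand <- lapply(1:2, function(i) make_part(sample(1:4, 20, replace = TRUE)))
  cons3 <- suppressWarnings(
    consensus_partition(structure(rand, class = "partition_ensemble"),
                        seed = 3, n_iter = 20))
  expect_true(is.logical(cons3$converged))
  expect_length(cons3$assignment, 20)
})

test_that("hierarchical clustering recovers planted and nested families", {
  lib <- generate_event_pattern_library(10, planted_modes_3(), noise_sd = 0.3,
                                        seed = 11)
  h <- hierarchical_cluster_events(concordance_matrix(lib$ensemble),
                                   n_iter = 100, n_perm = 200, seed = 4)
  aris <- vapply(h$levels, adjusted_rand_index, numeric(1), b = lib$family)
  expect_equal(max(aris), 1)

  # homogeneous ensemble: no significant subdivision, depth 1
  lib0 <- generate_event_pattern_library(10, planted_modes_3()[1],
                                         noise_sd = 0, seed = 3)
  h0 <- hierarchical_cluster_events(concordance_matrix(lib0$ensemble),
                                    n_iter = 50, n_perm = 200, seed = 4)
  expect_equal(h0$depth, 1L)

  # nested 2 -> 4 design
  libn <- generate_event_pattern_library(15, nested_modes(), noise_sd = 0.1,
                                         seed = 5)
  super <- rep(c(1, 1, 2, 2), each = 15)
  hn <- hierarchical_cluster_events(concordance_matrix(libn$ensemble),
                                    n_iter = 100, n_perm = 500, seed = 6)
  expect_gte(hn$depth, 3)
  expect_equal(max(hn$levels[[2]]), 2L)
  expect_equal(adjusted_rand_index(hn$levels[[2]], super), 1)
  expect_equal(max(hn$levels[[3]]), 4L)
  expect_equal(adjusted_rand_index(hn$levels[[3]], libn$family), 1)

  # sum of q_c equals Q at every level
  for (L in seq_len(hn$depth)) {
    expect_lt(abs(sum(hn$q_contributions[[L]]) - hn$Q_levels[L]), 1e-10)
  }
  # each level refines its parent: parent_map is well-formed
  for (L in seq(2, hn$depth)) {
    expect_length(hn$parent_map[[L]], max(hn$levels[[L]]))
    expect_true(all(hn$parent_map[[L]] >= 1 &
                      hn$parent_map[[L]] <= max(hn$levels[[L - 1]])))
  }
})

test_that("clustering is order-invariant and sign-flip invariant", {
  lib <- generate_event_pattern_library(8, planted_modes_3()[1:2],
                                        noise_sd = 0.3, seed = 21)
  cm <- concordance_matrix(lib$ensemble)
  h <- hierarchical_cluster_events(cm, n_iter = 50, n_perm = 100, seed = 9)

  set.seed(22)
  perm <- sample(lib$ensemble$M)
  ens_p <- pattern_ensemble(lib$ensemble$patterns[perm])
  hp <- hierarchical_cluster_events(concordance_matrix(ens_p), n_iter = 50,
                                    n_perm = 100, seed = 9)
  expect_equal(adjusted_rand_index(hp$levels[[min(2, hp$depth)]],
                                   h$levels[[min(2, h$depth)]][perm]), 1)

  # flipping an activation mode's sign leaves pattern and assignment unchanged
  v <- planted_modes_3()[[1]]
  pflip <- cofluct_pattern(tcrossprod(-v))
  porig <- cofluct_pattern(tcrossprod(v))
  expect_identical(unclass(pflip), unclass(porig))
})

test_that("centroids are groupwise means with correct member accounting", {
  lib <- generate_event_pattern_library(5, planted_modes_3()[1:2],
                                        noise_sd = 0.2, seed = 31)
  set.seed(32)
  lab <- sample(1:3, 10, replace = TRUE)
  lab <- cofluct:::canonical_labels(lab)
  cs <- compute_centroids(lib$ensemble, lab)
  expect_equal(sum(cs$member_fraction), 1)
  for (c_id in seq_along(cs$centroids)) {
    members <- which(lab == c_id)
    manual <- Reduce(`+`, lapply(lib$ensemble$patterns[members], unclass)) /
      length(members)
    expect_equal(unclass(cs$centroids[[c_id]]), manual, ignore_attr = TRUE)
  }
  # single-member cluster centroid equals the member
  one <- compute_centroids(lib$ensemble, c(1L, rep(2L, 9)))
  expect_equal(unclass(one$centroids[[1]]),
               unclass(lib$ensemble$patterns[[1]]), ignore_attr = TRUE)
  # noise-free rank-1 family centroid equals vv^T with zero diagonal
  v <- planted_modes_3()[[2]]
  lib0 <- generate_event_pattern_library(4, list(v), noise_sd = 0, seed = 1)
  c0 <- compute_centroids(lib0$ensemble, rep(1L, 4))
  expected <- tcrossprod(v)
  diag(expected) <- 0
  expect_equal(unclass(c0$centroids[[1]]), expected, ignore_attr = TRUE)
})
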