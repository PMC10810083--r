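test_that("structural connectome validates and computes strengths", {
  sc <- random_connectome(8, seed = 71)
  expect_equal(sum(sc$in_strength), sum(sc$out_strength))
  expect_equal(sum(sc$in_strength), sc$two_m)
  bad <- matrix(1, 3, 3)
  expect_error(structural_connectome(bad), "diagonal")
  bad2 <- matrix(0, 3, 3)
  bad2[1, 2] <- -1
  expect_error(structural_connectome(bad2), "non-negative")
})

test_that("bipartition extraction recovers a planted mode and errors on degeneracy", {
  # rank-1 centroid with mixed-sign v: labels equal sign(v), none empty
  v <- c(rep(1, 6), rep(-1, 6))
  bp <- extract_bipartition(cofluct_pattern(tcrossprod(v)), n_iter = 30,
                            seed = 1)
  expect_equal(bp$n_plus + bp$n_minus, 12L)
  expect_true(all((bp$labels == "plus") == (v > 0)) ||
                all((bp$labels == "plus") == (v < 0)))

  # all-positive centroid: no anticorrelated pair
  expect_error(
    extract_bipartition(cofluct_pattern(tcrossprod(abs(v) + 1)), n_iter = 30,
                        seed = 1),
    "no valid bipartition")

  # noisy planted mode: >= 95% label agreement
  set.seed(72)
  v40 <- c(rep(1, 20), rep(-1, 20))
  noisy <- Reduce(`+`, lapply(1:20, function(i) {
    u <- v40 + rnorm(40, sd = 0.4)
    tcrossprod(u)
  })) / 20
  bp2 <- extract_bipartition(cofluct_pattern(noisy), n_iter = 100, seed = 2)
  agree <- mean((bp2$labels == "plus") == (v40 > 0))
  expect_gte(max(agree, 1 - agree), 0.95)
})

test_that("induced modularity matches a literal double-loop oracle", {
  set.seed(73)
  for (k in 1:20) {
    n <- sample(5:8, 1)
    w <- matrix(runif(n * n) * rbinom(n * n, 1, 0.7), n, n)
    diag(w) <- 0
    sc <- structural_connectome(w)
    sizes <- c(2, 2)
    pick <- sample(n, 4)
    plus <- pick[1:2]
    minus <- pick[3:4]
    lab <- rep("none", n)
    lab[plus] <- "plus"
    lab[minus] <- "minus"
    bp <- bipartition(lab)
    expect_equal(induced_modularity(sc, bp), oracle_induced(w, plus, minus),
                 tolerance = 1e-10)
    # invariance to swapping plus/minus
    lab2 <- lab
    lab2[plus] <- "minus"
    lab2[minus] <- "plus"
    expect_equal(induced_modularity(sc, bipartition(lab2)),
                 induced_modularity(sc, bp), tolerance = 1e-12)
  }
})

test_that("uniform complete digraph gives the analytic induced modularity", {
  n <- 8
  w <- matrix(0.5, n, n)
  diag(w) <- 0
  sc <- structural_connectome(w)
  lab <- c(rep("plus", 3), rep("minus", 3), rep("none", 2))
  bp <- bipartition(lab)
  # closed form: every off-diagonal B = 0.5 - (0.5(n-1))^2 / (0.5 n (n-1))
  b_off <- 0.5 - (0.5 * (n - 1))^2 / (0.5 * n * (n - 1))
  analytic <- b_off * (3 * 2 + 3 * 2)
  expect_equal(induced_modularity(sc, bp), analytic, tolerance = 1e-10)

  # full-partition algebraic identity: the sum of B over ALL ordered pairs
  # (diagonal included) is exactly 0 because sum k_in = sum k_out = 2m
  Bsc <- cofluct:::sc_modularity_matrix(random_connectome(9, seed = 78))
  expect_equal(sum(Bsc), 0, tolerance = 1e-10)
})

test_that("Q_induced is invariant under consistent node relabeling", {
  set.seed(74)
  sc <- random_connectome(10, seed = 75)
  lab <- c(rep("plus", 4), rep("minus", 4), rep("none", 2))
  bp <- bipartition(lab)
  q <- induced_modularity(sc, bp)
  perm <- sample(10)
  sc_p <- structural_connectome(sc$weights[perm, perm])
  bp_p <- bipartition(lab[perm])
  expect_equal(induced_modularity(sc_p, bp_p), q, tolerance = 1e-10)
})

test_that("independent permutation null converges to exhaustive enumeration", {
  set.seed(76)
  w <- matrix(runif(36), 6, 6)
  diag(w) <- 0
  sc <- structural_connectome(w)
  lab <- c("plus", "plus", "minus", "minus", "none", "none")
  bp <- bipartition(lab)
  exact <- enumerate_induced_null(w, 2, 2)
  q_obs <- induced_modularity(sc, bp)
  p_exact <- mean(exact >= q_obs - 1e-12)
  res <- independent_permutation_null(sc, bp, n_perm = 4000, seed = 3)
  expect_lt(abs(res$p_value - p_exact), 0.03)
})

test_that("independent null p-values are uniform without planted structure", {
  set.seed(77)
  lab <- c(rep("plus", 8), rep("minus", 8), rep("none", 14))
  ps <- vapply(1:60, function(k) {
    sc <- random_connectome(30, seed = 600 + k)
    independent_permutation_null(sc, bipartition(sample(lab)), n_perm = 99,
                                 seed = k)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("rotation null preserves sizes, honors offset 0, and planted bipartition beats rotations", {
  d <- generate_modular_connectome(synth_config(seed = 23))
  truth <- d$truth
  lab <- ifelse(truth$module_labels == 1, "plus", "minus")
  bp <- bipartition(lab)
  # offset 0 is the identity labeling
  ord <- order(atan2(truth$node_coordinates[, 2], truth$node_coordinates[, 1]))
  expect_equal(cofluct:::rotate_labels(lab, ord, 0), lab)
  q_obs <- induced_modularity(d$sc, bp)
  # planted bipartition >= every ring rotation of itself
  qs <- vapply(1:39, function(s) {
    rl <- cofluct:::rotate_labels(lab, ord, s)
    induced_modularity(d$sc, bipartition(rl))
  }, numeric(1))
  # rotation by 20 swaps plus/minus exactly (equal Q up to summation order)
  expect_true(all(q_obs >= qs - 1e-8))

  res <- geometry_preserving_null(d$sc, bp, truth$node_coordinates,
                                  n_perm = 200, strategy = "rotation",
                                  seed = 5)
  # every surrogate preserves community sizes by construction; check via a
  # direct draw
  rl <- cofluct:::rotate_labels(lab, ord, 7)
  expect_equal(sum(rl == "plus"), bp$n_plus)
  expect_equal(sum(rl == "minus"), bp$n_minus)
  expect_lt(res$p_value, 0.05)

  # rotation null is stricter than the independent null on contiguous modules
  ind <- independent_permutation_null(d$sc, bp, n_perm = 200, seed = 5)
  expect_gt(mean(res$null_values), mean(ind$null_values))
})

test_that("variogram null accepts size-preserving surrogates and errors when too strict", {
  d <- generate_modular_connectome(synth_config(seed = 29))
  lab <- ifelse(d$truth$module_labels == 1, "plus", "minus")
  bp <- bipartition(lab)
  res <- geometry_preserving_null(d$sc, bp, d$truth$node_coordinates,
                                  n_perm = 50, strategy = "variogram",
                                  seed = 6, tolerance = 10)
  expect_length(res$null_values, 50)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_error(
    geometry_preserving_null(d$sc, bp, d$truth$node_coordinates,
                             n_perm = 50, strategy = "variogram", seed = 6,
                             tolerance = 1e-6, attempt_factor = 2L),
    "surrogates accepted")
})

test_that("gamma sweep reports invalid gammas and is stable for rank-1 centroids", {
  v <- c(rep(1, 10), rep(-1, 10))
  cen <- cofluct_pattern(tcrossprod(v))
  sc <- random_connectome(20, seed = 81)
  coords <- cbind(cos(2 * pi * (1:20) / 20), sin(2 * pi * (1:20) / 20))
  sweep <- gamma_sweep(cen, sc, coords, gammas = c(0.5, 1, 2), n_iter = 30,
                       n_perm = 50, seed = 2)
  expect_length(sweep, 3)
  labs <- lapply(sweep, function(r) {
    expect_true(r$valid)
    r$bipartition$labels
  })
  # noise-free rank-1 block structure: identical bipartition across gammas
  expect_equal(labs[[1]], labs[[2]])
  expect_equal(labs[[2]], labs[[3]])

  # single-gamma call path equivalence
  single <- gamma_sweep(cen, sc, coords, gammas = 1, n_iter = 30, n_perm = 50,
                        seed = 2)
  expect_equal(single[[1]]$bipartition$labels, labs[[2]])
})

test_that("coupling series matches a per-frame rank-correlation oracle", {
  d <- simulate_dataset(quick_config(seed = 9))
  z <- standardize_timeseries(d$ts)
  ets <- compute_edge_timeseries(z)
  rms <- compute_rms(ets)
  coup <- coupling_timeseries(ets, d$sc, rms)
  w_sym <- (d$sc$weights + t(d$sc$weights)) / 2
  sc_vec <- w_sym[ets$edge_index]
  for (t in c(1, 50, 200)) {
    expect_equal(coup$coupling[t],
                 cor(ets$values[, t], sc_vec, method = "spearman"),
                 tolerance = 1e-12)
  }
  # SC that is a monotone transform of a frame's pattern -> coupling exactly
  # 1 at that frame (Spearman is rank-based)
  pat <- unclass(frame_pattern(ets, 5))
  w2 <- exp(pat)
  diag(w2) <- 0
  coup2 <- coupling_timeseries(ets, structural_connectome(w2), rms)
  expect_equal(coup2$coupling[5], 1)
  expect_error(coupling_timeseries(
    ets, structural_connectome(matrix(0, d$config$n_nodes,
                                      d$config$n_nodes) +
                                 1 - diag(d$config$n_nodes)), rms),
    "constant")
})
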