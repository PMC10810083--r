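# Structure-function analysis: the bipartition implied by an event-cluster
# centroid, the modularity it induces on the directed weighted structural
# connectome (Q_induced), independent and geometry-preserving permutation
# nulls, and time-varying structure-function coupling.

#' Directed weighted structural connectome
#'
#' @param weights N x N non-negative matrix with zero diagonal; entry (i, j)
#'   is the weight of the directed connection i -> j
#' @return object of class `structural_connectome` with `weights`,
#'   `in_strength` (k_in(i) = sum_j W_ij), `out_strength`
#'   (k_out(i) = sum_j W_ji), `two_m` (sum of all weights), `N`
#' @export
structural_connectome <- function(weights) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights)) {
    stop("weights must be a square matrix")
  }
  if (any(weights < 0)) stop("connectome weights must be non-negative")
  if (any(diag(weights) != 0)) stop("connectome diagonal must be exactly zero")
  structure(list(weights = weights,
                 in_strength = rowSums(weights),
                 out_strength = colSums(weights),
                 two_m = sum(weights),
                 N = nrow(weights)),
            class = "structural_connectome")
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat(sprintf("<structural_connectome> %d nodes, total weight %.4g, density %.3f\n",
              x$N, x$two_m, mean(x$weights[row(x$weights) != col(x$weights)] > 0)))
  invisible(x)
}

# Directed modularity matrix B^sc_ij = W_ij - k_in(i) k_out(j) / 2m, built on
# the FULL connectome's strengths (never re-derived on a subgraph).
sc_modularity_matrix <- function(sc) {
  stopifnot(inherits(sc, "structural_connectome"))
  sc$weights - outer(sc$in_strength, sc$out_strength) / sc$two_m
}

#' Bipartition container
#'
#' @param labels per-node labels in `c("plus", "minus", "none")`
#' @param gamma_used resolution used to extract it
#' @return object of class `bipartition` with `labels`, `n_plus`, `n_minus`,
#'   `gamma_used`
#' @export
bipartition <- function(labels, gamma_used = NA_real_) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("plus", "minus", "none")))
  n_plus <- sum(labels == "plus")
  n_minus <- sum(labels == "minus")
  if (n_plus == 0 || n_minus == 0) {
    stop("bipartition requires non-empty plus and minus sets")
  }
  structure(list(labels = labels, n_plus = n_plus, n_minus = n_minus,
                 gamma_used = gamma_used),
            class = "bipartition")
}

#' Extract the bipartition implied by a co-fluctuation centroid
#'
#' Clusters the centroid with modularity maximization against a uniform null
#' (B = W - gamma * P, P = mean off-diagonal centroid value) plus consensus,
#' then takes the two largest communities, requires their mean inter-community
#' centroid value to be negative (anticorrelated groups), and labels them
#' `plus` (larger mean within-block value) and `minus`; all remaining nodes
#' are `none`. When several communities tie for the two largest sizes, the
#' pair with the most negative inter-community mean is chosen.
#'
#' @param centroid a [cofluct_pattern()]
#' @param gamma resolution parameter scaling P (default 1)
#' @param n_iter Louvain runs (default 1000)
#' @param seed integer seed
#' @return a [bipartition()]
#' @export
extract_bipartition <- function(centroid, gamma = 1, n_iter = 1000L, seed = 1L) {
  W <- unclass(centroid)
  n <- nrow(W)
  P <- mean(W[row(W) != col(W)])
  B <- W - gamma * P
  attr(B, "B_description") <- sprintf("centroid - %g * mean off-diagonal", gamma)
  ens <- maximize_modularity(B, n_iter = n_iter, seed = derive_seed(seed, "bip-louvain"))
  cons <- consensus_partition(ens, seed = derive_seed(seed, "bip-consensus"),
                              n_iter = n_iter)
  lab <- cons$assignment
  k <- max(lab)
  if (k < 2) {
    stop("no valid bipartition at this gamma: consensus found a single community")
  }
  sizes <- tabulate(lab, k)
  cutoff <- sort(sizes, decreasing = TRUE)[2]
  cand <- which(sizes >= cutoff)
  inter_mean <- function(a, b) mean(W[lab == a, lab == b])
  pairs <- utils::combn(cand, 2)
  vals <- apply(pairs, 2, function(pr) inter_mean(pr[1], pr[2]))
  # among candidate pairs covering the two largest sizes, most negative
  # inter-community mean wins
  pair_sizes <- apply(pairs, 2, function(pr) sum(sizes[pr]))
  keep <- which(pair_sizes == max(pair_sizes))
  best <- keep[which.min(vals[keep])]
  if (vals[best] >= 0) {
    stop("no valid bipartition at this gamma: the two largest communities ",
         "are not anticorrelated (mean inter-community value ",
         signif(vals[best], 3), " >= 0)")
  }
  a <- pairs[1, best]
  b <- pairs[2, best]
  within_mean <- function(cc) {
    sub <- W[lab == cc, lab == cc, drop = FALSE]
    mean(sub[row(sub) != col(sub)])
  }
  plus_comm <- if (within_mean(a) >= within_mean(b)) a else b
  minus_comm <- if (plus_comm == a) b else a
  labels <- rep("none", n)
  labels[lab == plus_comm] <- "plus"
  labels[lab == minus_comm] <- "minus"
  bipartition(labels, gamma_used = gamma)
}

#' Modularity a bipartition induces on the structural connectome
#'
#' Q_induced = sum over ordered pairs within the plus community of B^sc plus
#' the same sum within the minus community, with
#' B^sc_ij = W^sc_ij - k_in(i) k_out(j) / 2m built from the full connectome's
#' strengths and diagonal terms excluded. Invariant to swapping plus/minus.
#'
#' @param sc a [structural_connectome()]
#' @param bp a [bipartition()]
#' @return scalar Q_induced
#' @export
induced_modularity <- function(sc, bp) {
  stopifnot(inherits(sc, "structural_connectome"), inherits(bp, "bipartition"))
  if (length(bp$labels) != sc$N) stop("bipartition and connectome disagree on N")
  Bsc <- sc_modularity_matrix(sc)
  induced_modularity_from_sets(Bsc, which(bp$labels == "plus"),
                               which(bp$labels == "minus"))
}

# core sum, reused by the permutation nulls (Bsc precomputed once)
induced_modularity_from_sets <- function(Bsc, plus, minus) {
  if (!length(plus) || !length(minus)) stop("empty bipartition community")
  sum(Bsc[plus, plus]) - sum(diag(Bsc)[plus]) +
    sum(Bsc[minus, minus]) - sum(diag(Bsc)[minus])
}

modularity_result <- function(Q, null_values, p, kind, n_perm, seed) {
  structure(list(Q_induced = Q, null_values = null_values, p_value = p,
                 null_kind = kind, n_perm = n_perm, seed = seed),
            class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("<modularity_result> Q_induced = %.4f, %s null: p = %.4g (n_perm = %d)\n",
              x$Q_induced, x$null_kind, x$p_value, x$n_perm))
  invisible(x)
}

#' Independent permutation null for induced modularity
#'
#' Each permutation draws disjoint node sets of the observed sizes n_plus and
#' n_minus uniformly from all N nodes (no spatial constraint) and recomputes
#' Q_induced; p = (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' @param sc a [structural_connectome()]
#' @param bp the observed [bipartition()]
#' @param n_perm number of permutations (default 1000)
#' @param seed integer seed
#' @return a `modularity_result` (`null_kind = "independent"`)
#' @export
independent_permutation_null <- function(sc, bp, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(sc, "structural_connectome"), inherits(bp, "bipartition"))
  if (bp$n_plus + bp$n_minus > sc$N) stop("n_plus + n_minus exceeds N")
  Bsc <- sc_modularity_matrix(sc)
  q_obs <- induced_modularity(sc, bp)
  with_seed(seed, {
    null_q <- vapply(seq_len(n_perm), function(r) {
      pick <- sample.int(sc$N, bp$n_plus + bp$n_minus)
      induced_modularity_from_sets(Bsc, pick[seq_len(bp$n_plus)],
                                   pick[(bp$n_plus + 1):length(pick)])
    }, numeric(1))
    p <- (1 + sum(null_q >= q_obs)) / (1 + n_perm)
    modularity_result(q_obs, null_q, p, "independent", as.integer(n_perm), seed)
  })
}

# Rotate a label vector along a spatial ordering by `offset` positions.
rotate_labels <- function(labels, order_idx, offset) {
  n <- length(labels)
  out <- labels
  shifted <- order_idx[((seq_len(n) - 1 + offset) %% n) + 1]
  out[shifted] <- labels[order_idx]
  out
}

# Binned variogram of a numeric indicator vector over pairwise distances.
label_variogram <- function(v, dmat, breaks) {
  iu <- edge_index(length(v))
  d <- dmat[iu]
  g2 <- (v[iu[, 1]] - v[iu[, 2]])^2 / 2
  bin <- cut(d, breaks, include.lowest = TRUE)
  tapply(g2, bin, mean)
}

#' Geometry-preserving permutation null for induced modularity
#'
#' `rotation` (for ring-like layouts): the plus/minus/none label vector is
#' rotated by a random non-zero offset along the angular ordering of the
#' nodes, exactly preserving community sizes and spatial contiguity.
#' `variogram`: uniform random permutations of the label vector are accepted
#' only when the binned variogram of the label indicator (plus = 1,
#' minus = 2, none = 0) matches the original within `tolerance` relative
#' error, approximately preserving spatial autocorrelation; generation fails
#' with an error if `attempt_factor * n_perm` proposals do not yield `n_perm`
#' accepted surrogates.
#'
#' @param sc a [structural_connectome()]
#' @param bp the observed [bipartition()]
#' @param coordinates N x 2 node coordinates
#' @param n_perm number of surrogates (default 1000)
#' @param strategy `"rotation"` or `"variogram"`
#' @param seed integer seed
#' @param tolerance variogram relative-error tolerance (default 0.1)
#' @param attempt_factor proposal oversampling cap (default 50)
#' @param n_bins distance bins for the variogram (default 10)
#' @return a `modularity_result` (`null_kind = "rotation"` or `"variogram"`)
#' @export
geometry_preserving_null <- function(sc, bp, coordinates, n_perm = 1000L,
                                     strategy = c("rotation", "variogram"),
                                     seed = 1L, tolerance = 0.1,
                                     attempt_factor = 50L, n_bins = 10L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(sc, "structural_connectome"), inherits(bp, "bipartition"))
  if (nrow(coordinates) != sc$N) stop("coordinates must cover all N nodes")
  Bsc <- sc_modularity_matrix(sc)
  q_obs <- induced_modularity(sc, bp)
  labels <- bp$labels
  n <- sc$N
  q_of_labels <- function(lv) {
    induced_modularity_from_sets(Bsc, which(lv == "plus"), which(lv == "minus"))
  }
  with_seed(derive_seed(seed, paste0("geom-", strategy)), {
    if (strategy == "rotation") {
      ctr <- colMeans(coordinates)
      ang <- atan2(coordinates[, 2] - ctr[2], coordinates[, 1] - ctr[1])
      order_idx <- order(ang)
      offsets <- sample.int(n - 1L, n_perm, replace = TRUE)
      null_q <- vapply(offsets, function(s) {
        q_of_labels(rotate_labels(labels, order_idx, s))
      }, numeric(1))
    } else {
      dmat <- as.matrix(stats::dist(coordinates))
      v <- c(none = 0, plus = 1, minus = 2)[labels]
      dvals <- dmat[edge_index(n)]
      breaks <- stats::quantile(dvals, probs = seq(0, 1, length.out = n_bins + 1))
      breaks <- unique(breaks)
      g0 <- label_variogram(v, dmat, breaks)
      null_q <- numeric(0)
      attempts <- 0L
      cap <- attempt_factor * n_perm
      while (length(null_q) < n_perm && attempts < cap) {
        attempts <- attempts + 1L
        perm <- sample.int(n)
        vs <- v[perm]
        gs <- label_variogram(vs, dmat, breaks)
        rel <- abs(gs - g0) / pmax(abs(g0), 1e-12)
        if (all(rel <= tolerance, na.rm = TRUE)) {
          lv <- labels[perm]
          null_q <- c(null_q, q_of_labels(lv))
        }
      }
      if (length(null_q) < n_perm) {
        stop("variogram null: only ", length(null_q), " of ", n_perm,
             " surrogates accepted within ", cap, " attempts; ",
             "loosen `tolerance` or use strategy = \"rotation\"")
      }
    }
    p <- (1 + sum(null_q >= q_obs)) / (1 + length(null_q))
    modularity_result(q_obs, null_q, p, strategy, as.integer(n_perm), seed)
  })
}

#' Sweep the bipartition resolution parameter
#'
#' Runs [extract_bipartition()] and both permutation nulls at each gamma.
#' Gammas where no valid bipartition exists are reported (`valid = FALSE`),
#' not raised.
#'
#' @param centroid a [cofluct_pattern()]
#' @param sc a [structural_connectome()]
#' @param coordinates N x 2 node coordinates
#' @param gammas numeric vector of resolutions
#' @param n_iter,n_perm,seed passed through
#' @param geometry_strategy `"rotation"` or `"variogram"`
#' @return list of per-gamma records: `gamma`, `valid`, and when valid
#'   `bipartition`, `independent`, `geometry` (both `modularity_result`s)
#' @export
gamma_sweep <- function(centroid, sc, coordinates, gammas, n_iter = 1000L,
                        n_perm = 1000L, seed = 1L,
                        geometry_strategy = "rotation") {
  if (!length(gammas)) stop("gamma list must be non-empty")
  lapply(gammas, function(g) {
    bp <- tryCatch(
      extract_bipartition(centroid, gamma = g, n_iter = n_iter,
                          seed = derive_seed(seed, paste0("gamma", g))),
      error = function(e) e
    )
    if (inherits(bp, "error")) {
      return(list(gamma = g, valid = FALSE, reason = conditionMessage(bp)))
    }
    list(gamma = g, valid = TRUE, bipartition = bp,
         independent = independent_permutation_null(
           sc, bp, n_perm = n_perm, seed = derive_seed(seed, paste0("ind", g))),
         geometry = geometry_preserving_null(
           sc, bp, coordinates, n_perm = n_perm, strategy = geometry_strategy,
           seed = derive_seed(seed, paste0("geo", g))))
  })
}

#' Time-varying structure-function coupling
#'
#' Per frame, the Spearman rank correlation between the upper-triangle
#' co-fluctuation vector and the upper-triangle symmetrized structural
#' connectome (W + W^T)/2, paired with the frame's RMS amplitude.
#'
#' @param ets an `edge_ts`
#' @param sc a [structural_connectome()] on the same nodes
#' @param rms the matching `rms_series`
#' @return data.frame of class `coupling_series`: `frame`, `coupling`, `rms`
#' @export
coupling_timeseries <- function(ets, sc, rms) {
  stopifnot(inherits(ets, "edge_ts"), inherits(sc, "structural_connectome"))
  if (ets$N != sc$N) stop("edge time series and connectome disagree on N")
  w_sym <- (sc$weights + t(sc$weights)) / 2
  sc_vec <- w_sym[ets$edge_index]
  if (stats::sd(sc_vec) == 0) {
    stop("coupling undefined: symmetrized connectome edge weights are constant")
  }
  coupling <- as.numeric(stats::cor(ets$values, sc_vec, method = "spearman"))
  out <- data.frame(frame = seq_len(ets$T), coupling = coupling,
                    rms = as.numeric(rms))
  class(out) <- c("coupling_series", class(out))
  out
}
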