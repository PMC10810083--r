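# Planted-structure synthetic data: a modular directed weighted connectome on
# a spatial layout, serially correlated nodal signals whose covariance follows
# the planted modules, rare injected high-amplitude frames driven by a
# module-contrast activation mode, and rank-1 pattern libraries for clustering
# fixtures. Ground truth is returned alongside every generated object so each
# downstream stage can be scored against what was planted.

#' Configuration for the synthetic generators
#'
#' Defaults define the package's reference synthetic world: two contiguous
#' 20-node modules on a ring, 1000 frames of AR(1) signal (coefficient 0.3)
#' with block correlation 0.3 within / 0 between modules, and 20 injected
#' events of amplitude 4 baseline-SD units on a +1/-1 module-contrast mode.
#'
#' @param n_nodes number of parcels N
#' @param module_sizes integer vector summing to `n_nodes`, each entry >= 2
#' @param within_weight_mean,between_weight_mean mean connection weight for
#'   node pairs inside / across modules (non-negative)
#' @param weight_noise_sd SD of Gaussian weight noise (weights clipped at 0)
#' @param density_within,density_between Bernoulli edge-presence probabilities
#' @param n_frames number of frames T
#' @param ar_coefficient AR(1) serial-correlation coefficient in [0, 1)
#' @param rho_within baseline within-module correlation in [0, 1)
#' @param rho_between baseline between-module correlation in (-1, 1)
#' @param n_events number of injected high-amplitude frames
#' @param event_amplitude additive event amplitude in baseline-SD units
#' @param event_mode_noise_sd SD of Gaussian perturbation of the +1/-1 mode
#' @param geometry `"ring"` (nodes at equal angles, modules contiguous arcs)
#'   or `"grid"` (square lattice, modules contiguous in row-major order)
#' @param seed integer seed; every generator taking this config is
#'   bit-reproducible given it
#' @return validated list of class `synth_config`
#' @export
synth_config <- function(n_nodes = 40L,
                         module_sizes = c(20L, 20L),
                         within_weight_mean = 1.0,
                         between_weight_mean = 0.25,
                         weight_noise_sd = 0.2,
                         density_within = 0.6,
                         density_between = 0.3,
                         n_frames = 1000L,
                         ar_coefficient = 0.3,
                         rho_within = 0.3,
                         rho_between = 0.0,
                         n_events = 20L,
                         event_amplitude = 4,
                         event_mode_noise_sd = 0.25,
                         geometry = c("ring", "grid"),
                         seed = 7L) {
  geometry <- match.arg(geometry)
  cfg <- list(
    n_nodes = as.integer(n_nodes), module_sizes = as.integer(module_sizes),
    within_weight_mean = within_weight_mean,
    between_weight_mean = between_weight_mean,
    weight_noise_sd = weight_noise_sd,
    density_within = density_within, density_between = density_between,
    n_frames = as.integer(n_frames), ar_coefficient = ar_coefficient,
    rho_within = rho_within, rho_between = rho_between,
    n_events = as.integer(n_events), event_amplitude = event_amplitude,
    event_mode_noise_sd = event_mode_noise_sd,
    geometry = geometry, seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (sum(module_sizes) != n_nodes) {
      stop("sum(module_sizes) = ", sum(module_sizes),
           " must equal n_nodes = ", n_nodes)
    }
    if (any(module_sizes < 2)) stop("degenerate config: every module needs >= 2 nodes")
    if (within_weight_mean < 0 || between_weight_mean < 0 || weight_noise_sd < 0) {
      stop("weight parameters must be non-negative")
    }
    if (density_within < 0 || density_within > 1 ||
        density_between < 0 || density_between > 1) {
      stop("densities must lie in [0, 1]")
    }
    if (ar_coefficient < 0 || ar_coefficient >= 1) {
      stop("ar_coefficient must lie in [0, 1)")
    }
    if (rho_within < 0 || rho_within >= 1) stop("rho_within must lie in [0, 1)")
    if (rho_between <= -1 || rho_between >= 1) stop("rho_between must lie in (-1, 1)")
    if (event_amplitude < 0 || event_mode_noise_sd < 0) {
      stop("event parameters must be non-negative")
    }
    if (n_frames < 3) stop("n_frames must be >= 3")
  })
  # Block covariance must be positive semi-definite at construction.
  sigma <- block_covariance(cfg$module_sizes, cfg$rho_within, cfg$rho_between)
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    stop("implied baseline covariance is not positive semi-definite ",
         "(min eigenvalue ", signif(ev, 3), "); adjust rho_within/rho_between")
  }
  invisible(cfg)
}

# Unit-diagonal block covariance: rho_within inside modules, rho_between across.
block_covariance <- function(module_sizes, rho_within, rho_between) {
  labels <- rep(seq_along(module_sizes), module_sizes)
  same <- outer(labels, labels, "==")
  sigma <- ifelse(same, rho_within, rho_between)
  diag(sigma) <- 1
  sigma
}

module_labels_of <- function(cfg) {
  rep(seq_along(cfg$module_sizes), cfg$module_sizes)
}

# Node coordinates: ring = unit circle at equal angles (distance = chord
# length), grid = unit-spaced square lattice in row-major order. Module labels
# are contiguous in node order, so modules are spatially contiguous by design.
layout_coordinates <- function(n_nodes, geometry) {
  if (geometry == "ring") {
    theta <- 2 * pi * (seq_len(n_nodes) - 1) / n_nodes
    cbind(x = cos(theta), y = sin(theta))
  } else {
    side <- ceiling(sqrt(n_nodes))
    k <- seq_len(n_nodes) - 1L
    cbind(x = k %% side, y = k %/% side)
  }
}

#' Ground-truth record for synthetic data
#' @param module_labels per-node planted community id (1-based)
#' @param node_coordinates N x 2 coordinate matrix
#' @param event_frames sorted unique injected frame indices (1-based), or
#'   integer(0) before time-series generation
#' @param event_modes N x n_events matrix of realized signed activation
#'   vectors, or NULL
#' @return object of class `ground_truth`
#' @export
ground_truth <- function(module_labels, node_coordinates,
                         event_frames = integer(0), event_modes = NULL) {
  stopifnot(nrow(node_coordinates) == length(module_labels))
  if (length(event_frames)) {
    stopifnot(!anyDuplicated(event_frames), !is.unsorted(event_frames))
  }
  structure(list(module_labels = as.integer(module_labels),
                 node_coordinates = node_coordinates,
                 event_frames = as.integer(event_frames),
                 event_modes = event_modes),
            class = "ground_truth")
}

#' Generate a planted modular directed weighted connectome
#'
#' Ordered node pairs (i, j), i != j, receive a connection with probability
#' `density_within` (same module) or `density_between` (different modules);
#' present weights are Gaussian around the stated means, clipped at zero.
#' Diagonal is exactly zero. Nodes are laid out so modules are spatially
#' contiguous (arcs of a ring or blocks of a grid).
#'
#' @param config a [synth_config()]
#' @return list with `sc` (a [structural_connectome()]) and `truth`
#'   (a [ground_truth()]; `event_frames`/`event_modes` empty at this stage)
#' @export
generate_modular_connectome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_nodes
  labels <- module_labels_of(config)
  coords <- layout_coordinates(n, config$geometry)
  with_seed(derive_seed(config$seed, "connectome"), {
    same <- outer(labels, labels, "==")
    p <- ifelse(same, config$density_within, config$density_between)
    mu <- ifelse(same, config$within_weight_mean, config$between_weight_mean)
    present <- matrix(stats::runif(n * n) < p, n, n)
    w <- matrix(stats::rnorm(n * n, mean = mu, sd = config$weight_noise_sd), n, n)
    w <- pmax(w, 0) * present
    diag(w) <- 0
    list(sc = structural_connectome(w),
         truth = ground_truth(labels, coords))
  })
}

#' Generate serially correlated parcel time series with injected events
#'
#' Baseline: stationary AR(1) process (coefficient `ar_coefficient`) driven by
#' multivariate Gaussian innovations with block covariance (`rho_within`
#' within modules, `rho_between` between), rescaled so the stationary marginal
#' variance is 1 — `event_amplitude` is therefore in baseline-SD units. At
#' each of `n_events` frames (interior frames, minimum separation 3) an
#' additive component a * v is injected, where v is the +1/-1 module-contrast
#' vector perturbed by `event_mode_noise_sd`; realized modes are stored in the
#' returned ground truth.
#'
#' @param config a [synth_config()]
#' @param truth the [ground_truth()] from [generate_modular_connectome()]
#' @return list with `ts` (raw [parcel_ts()]) and `truth` (updated with
#'   `event_frames` and `event_modes`)
#' @export
generate_parcel_timeseries <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"), inherits(truth, "ground_truth"))
  n <- config$n_nodes
  t_len <- config$n_frames
  if (config$n_events >= t_len) {
    stop("n_events (", config$n_events, ") must be smaller than n_frames (",
         t_len, ")")
  }
  phi <- config$ar_coefficient
  sigma <- block_covariance(config$module_sizes, config$rho_within,
                            config$rho_between)
  ec <- eigen(sigma, symmetric = TRUE)
  cr <- ec$vectors %*% (sqrt(pmax(ec$values, 0)) * t(ec$vectors))
  with_seed(derive_seed(config$seed, "timeseries"), {
    innov <- cr %*% matrix(stats::rnorm(n * t_len), n, t_len)
    x <- matrix(0, n, t_len)
    # stationary start: x_1 ~ N(0, Sigma / (1 - phi^2))
    x[, 1] <- innov[, 1] / sqrt(1 - phi^2)
    if (t_len > 1) {
      for (t in 2:t_len) x[, t] <- phi * x[, t - 1] + innov[, t]
    }
    # renormalize the stationary marginal variance to 1
    x <- x * sqrt(1 - phi^2)
    frames <- integer(0)
    modes <- NULL
    if (config$n_events > 0) {
      frames <- sample_separated_frames(t_len, config$n_events, min_gap = 3L)
      base_mode <- ifelse(truth$module_labels %% 2 == 1, 1, -1)
      modes <- matrix(stats::rnorm(n * config$n_events, sd = config$event_mode_noise_sd),
                      n, config$n_events) + base_mode
      x[, frames] <- x[, frames] + config$event_amplitude * modes
    }
    list(ts = parcel_ts(x),
         truth = ground_truth(truth$module_labels, truth$node_coordinates,
                              frames, modes))
  })
}

# Draw k interior frames (2..t_len-1) pairwise separated by >= min_gap.
# Events are rare and isolated; boundary frames can never be RMS peaks.
sample_separated_frames <- function(t_len, k, min_gap = 3L) {
  pool <- seq(2L, t_len - 1L)
  picked <- integer(0)
  for (attempt in seq_len(1000L)) {
    cand <- sort(sample(pool, k))
    if (k < 2 || min(diff(cand)) >= min_gap) {
      picked <- cand
      break
    }
  }
  if (!length(picked)) {
    stop("could not place ", k, " events with separation ", min_gap,
         " in ", t_len, " frames")
  }
  picked
}

#' Generate a library of rank-1 co-fluctuation patterns with family labels
#'
#' Each pattern is (v + e)(v + e)^T with e ~ N(0, noise_sd^2) iid and the
#' diagonal zeroed, where v is one of the supplied activation modes. Because a
#' pattern is an outer product, v and -v yield the identical pattern (the sign
#' ambiguity of activation modes).
#'
#' @param n_patterns_per_family patterns generated per mode
#' @param modes list of non-constant numeric activation vectors, equal lengths
#' @param noise_sd Gaussian perturbation SD
#' @param seed integer seed
#' @return list with `ensemble` (a [pattern_ensemble()]) and `family` (integer
#'   label per pattern)
#' @export
generate_event_pattern_library <- function(n_patterns_per_family, modes,
                                           noise_sd = 0.1, seed = 1L) {
  if (!length(modes)) stop("modes list must be non-empty")
  n <- length(modes[[1]])
  for (v in modes) {
    if (length(v) != n) stop("all modes must have equal length")
    if (stats::sd(v) == 0) stop("modes must be non-constant")
  }
  with_seed(seed, {
    pats <- list()
    fam <- integer(0)
    for (f in seq_along(modes)) {
      for (k in seq_len(n_patterns_per_family)) {
        v <- modes[[f]] + stats::rnorm(n, sd = noise_sd)
        pats[[length(pats) + 1L]] <- cofluct_pattern(
          tcrossprod(v), source = "synthetic",
          subject_id = sprintf("family%d", f))
        fam <- c(fam, f)
      }
    }
    list(ensemble = pattern_ensemble(pats), family = fam)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_modular_connectome()] then
#' [generate_parcel_timeseries()].
#'
#' @param config a [synth_config()]
#' @return list with `ts`, `sc`, `truth`, `config`
#' @export
simulate_dataset <- function(config = synth_config()) {
  con <- generate_modular_connectome(config)
  tsr <- generate_parcel_timeseries(config, con$truth)
  list(ts = tsr$ts, sc = con$sc, truth = tsr$truth, config = config)
}
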