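# Edge dynamics: standardization, edge (co-fluctuation) time series, static
# FC, per-frame co-fluctuation patterns, and the RMS amplitude series.
#
# The conventions here make the decomposition identity exact: standardization
# uses the sample SD (denominator T-1) and static FC is the 1/(T-1) sum of the
# framewise products, so mean(ETS) == Pearson r to machine precision.

#' Parcel time series container
#'
#' An N x T matrix of nodal signals (rows = parcels, columns = frames).
#'
#' @param values numeric N x T matrix, no missing values, N >= 2, T >= 3
#' @param parcel_ids optional character labels, one per parcel
#' @param standardized logical; if `TRUE` each row is validated to have mean 0
#'   and sample standard deviation 1 (tolerance 1e-10)
#' @return object of class `parcel_ts` with fields `values`, `parcel_ids`,
#'   `standardized`, `N`, `T`
#' @export
parcel_ts <- function(values, parcel_ids = NULL, standardized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (parcels x frames)")
  }
  if (anyNA(values)) stop("parcel time series contains missing values")
  n <- nrow(values)
  t_len <- ncol(values)
  if (n < 2) stop("need at least 2 parcels, got ", n)
  if (t_len < 3) stop("need at least 3 frames, got ", t_len)
  if (is.null(parcel_ids)) parcel_ids <- paste0("parcel_", seq_len(n) - 1L)
  if (length(parcel_ids) != n) stop("parcel_ids length must equal N")
  if (standardized) {
    mu <- rowMeans(values)
    sdv <- apply(values, 1, stats::sd)
    if (any(abs(mu) >= 1e-10) || any(abs(sdv - 1) >= 1e-10)) {
      stop("standardized = TRUE but rows are not z-scored")
    }
  }
  structure(
    list(values = values, parcel_ids = as.character(parcel_ids),
         standardized = isTRUE(standardized), N = n, T = t_len),
    class = "parcel_ts"
  )
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> %d parcels x %d frames (%s)\n", x$N, x$T,
              if (x$standardized) "standardized" else "raw"))
  invisible(x)
}

#' z-score each parcel time series
#'
#' Rows are centered and scaled to sample standard deviation 1 (denominator
#' T-1). Idempotent on already-standardized input.
#'
#' @param ts a [parcel_ts()]
#' @return standardized `parcel_ts`
#' @export
standardize_timeseries <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  sdv <- apply(ts$values, 1, stats::sd)
  bad <- which(sdv == 0 | !is.finite(sdv))
  if (length(bad)) {
    stop("constant (zero-variance) parcel time series: ",
         paste(ts$parcel_ids[bad], collapse = ", "))
  }
  z <- (ts$values - rowMeans(ts$values)) / sdv
  parcel_ts(z, ts$parcel_ids, standardized = TRUE)
}

#' Edge (co-fluctuation) time series
#'
#' For every node pair (i, j), i < j, the framewise product
#' r_ij(t) = z_i(t) z_j(t) of the z-scored signals. Rows follow the row-major
#' upper-triangle order of [edge_index()]. The temporal mean of each row
#' (sum divided by T-1) is exactly the Pearson correlation of the two parcels,
#' so edge time series are an exact decomposition of static FC.
#'
#' @param ts standardized [parcel_ts()]
#' @return object of class `edge_ts`: `values` (E x T), `edge_index`
#'   (E x 2, 1-based), `N`, `T`
#' @export
compute_edge_timeseries <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (!ts$standardized) stop("edge time series require standardized input; call standardize_timeseries() first")
  idx <- edge_index(ts$N)
  vals <- ts$values[idx[, 1], , drop = FALSE] * ts$values[idx[, 2], , drop = FALSE]
  rownames(vals) <- NULL
  structure(list(values = vals, edge_index = idx, N = ts$N, T = ts$T),
            class = "edge_ts")
}

#' @export
print.edge_ts <- function(x, ...) {
  cat(sprintf("<edge_ts> %d edges (N = %d) x %d frames\n",
              nrow(x$values), x$N, x$T))
  invisible(x)
}

#' Static functional connectivity matrix
#'
#' r_ij = (1/(T-1)) * sum_t z_i(t) z_j(t), the product-moment correlation of
#' the raw rows. Symmetric with unit diagonal.
#'
#' @param ts standardized [parcel_ts()]
#' @return N x N correlation matrix of class `fc_matrix`
#' @export
compute_static_fc <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (!ts$standardized) stop("static FC requires standardized input")
  fc <- tcrossprod(ts$values) / (ts$T - 1)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  dimnames(fc) <- list(ts$parcel_ids, ts$parcel_ids)
  class(fc) <- c("fc_matrix", class(fc))
  fc
}

#' Co-fluctuation pattern at one frame
#'
#' The N x N symmetric matrix of all edge values at frame `t`; equals the
#' outer product of the frame's standardized activation vector with its
#' diagonal zeroed. The diagonal (squared activations) is excluded from every
#' pattern statistic in this package.
#'
#' @param ets an `edge_ts`
#' @param t frame index (1-based)
#' @param subject_id optional label carried on the pattern
#' @return N x N matrix of class `cofluct_pattern` with attributes `source`
#'   (the frame) and `subject_id`
#' @export
frame_pattern <- function(ets, t, subject_id = NA_character_) {
  stopifnot(inherits(ets, "edge_ts"))
  if (length(t) != 1 || t < 1 || t > ets$T) {
    stop("frame index out of range [1, ", ets$T, "]: ", t)
  }
  cofluct_pattern(unvec_sym(ets$values[, t], ets$N),
                  source = t, subject_id = subject_id)
}

#' Construct a co-fluctuation pattern object
#' @param m N x N symmetric numeric matrix; diagonal is forced to zero
#' @param source frame index or `"centroid"`
#' @param subject_id label
#' @return `cofluct_pattern`
#' @export
cofluct_pattern <- function(m, source = "centroid", subject_id = NA_character_) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8) stop("co-fluctuation pattern must be symmetric")
  diag(m) <- 0
  structure(m, source = source, subject_id = subject_id,
            class = c("cofluct_pattern", "matrix", "array"))
}

#' RMS co-fluctuation amplitude series
#'
#' RMS(t) = sqrt( (2 / (N(N-1))) * sum_{i<j} r_ij(t)^2 ): the root mean square
#' over all E edges at each frame, the global co-fluctuation magnitude.
#'
#' @param ets an `edge_ts`
#' @return non-negative numeric vector of length T, class `rms_series`
#' @export
compute_rms <- function(ets) {
  stopifnot(inherits(ets, "edge_ts"))
  structure(sqrt(colMeans(ets$values^2)), class = "rms_series")
}

# Fast RMS straight from the standardized N x T matrix without forming the
# E x T edge matrix, via sum_{i<j} (z_i z_j)^2 = ((sum z^2)^2 - sum z^4) / 2.
# Used by the circular-shift surrogate loop; equality with compute_rms() is
# asserted by a dedicated test.
rms_from_z <- function(z) {
  n <- nrow(z)
  s2 <- colSums(z^2)
  s4 <- colSums(z^4)
  structure(sqrt(pmax(s2^2 - s4, 0) / (n * (n - 1))), class = "rms_series")
}
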