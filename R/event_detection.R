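# Event detection: local extrema of the RMS co-fluctuation amplitude, a
# circular-shift surrogate null for peak heights, BH-FDR control within
# subject, frame categorization, and FC-reconstruction comparisons between
# frame categories.

#' Local extrema of an RMS series
#'
#' Peaks are interior frames strictly greater than both neighbors; troughs
#' strictly less. A plateau run that is a strict local maximum (minimum)
#' relative to the adjacent runs contributes its first frame only.
#'
#' @param rms numeric RMS series (length >= 3)
#' @return list of class `extrema_set` with sorted `peak_frames`,
#'   `trough_frames` (1-based) and matching `peak_amplitudes`,
#'   `trough_amplitudes`
#' @export
find_local_extrema <- function(rms) {
  x <- as.numeric(rms)
  if (length(x) < 3) stop("need at least 3 frames")
  r <- rle(x)
  k <- length(r$values)
  starts <- cumsum(c(1L, r$lengths[-k]))
  peak <- trough <- logical(k)
  if (k >= 3) {
    mid <- 2:(k - 1)
    peak[mid] <- r$values[mid] > r$values[mid - 1] & r$values[mid] > r$values[mid + 1]
    trough[mid] <- r$values[mid] < r$values[mid - 1] & r$values[mid] < r$values[mid + 1]
  }
  pf <- starts[peak]
  tf <- starts[trough]
  structure(list(peak_frames = pf, peak_amplitudes = x[pf],
                 trough_frames = tf, trough_amplitudes = x[tf]),
            class = "extrema_set")
}

# Circularly shift each row of z by its own offset (1..T-1).
circular_shift_rows <- function(z, offsets) {
  t_len <- ncol(z)
  out <- z
  for (i in seq_len(nrow(z))) {
    s <- offsets[i] %% t_len
    if (s > 0) out[i, ] <- z[i, c((t_len - s + 1):t_len, 1:(t_len - s))]
  }
  out
}

#' Null distribution of RMS peak amplitudes from circular-shift surrogates
#'
#' Per run, every parcel's z-scored series is independently circularly
#' shifted by a uniform random offset in 1..T-1 (offset 0 excluded), the RMS
#' series is recomputed, and its peak amplitudes are pooled across runs.
#' Circular shifting preserves each parcel's autocorrelation and marginal
#' distribution while destroying inter-parcel alignment.
#'
#' @param ts standardized [parcel_ts()]
#' @param n_runs number of surrogate runs (>= 1); 100 matches the package's
#'   default analysis, 1000 is available for stricter nulls
#' @param seed integer seed
#' @return list of class `null_peak_distribution` with pooled
#'   `null_peak_amplitudes`, `n_runs`, `seed`
#' @export
build_null_peak_distribution <- function(ts, n_runs = 100L, seed = 1L) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (!ts$standardized) stop("null construction requires standardized input")
  if (n_runs < 1) stop("n_runs must be >= 1")
  z <- ts$values
  with_seed(seed, {
    pooled <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      offsets <- sample.int(ts$T - 1L, ts$N, replace = TRUE)
      rms_null <- rms_from_z(circular_shift_rows(z, offsets))
      pooled[[r]] <- find_local_extrema(rms_null)$peak_amplitudes
    }
    structure(list(null_peak_amplitudes = unlist(pooled, use.names = FALSE),
                   n_runs = as.integer(n_runs), seed = as.integer(seed)),
              class = "null_peak_distribution")
  })
}

#' Detect events among RMS peaks
#'
#' Each empirical peak gets a non-parametric p-value against the pooled null,
#' p = (1 + #\{null >= amplitude\}) / (1 + #null) (add-one estimator, so p is
#' never 0). Benjamini-Hochberg is applied across the subject's peaks; peaks
#' with q <= `q_threshold` are flagged as events.
#'
#' @param extrema an `extrema_set`
#' @param null a `null_peak_distribution`
#' @param q_threshold FDR level (default 0.05)
#' @return data.frame of class `event_table` with columns `frame`,
#'   `amplitude`, `p_value`, `q_value`, `is_event`
#' @export
detect_events <- function(extrema, null, q_threshold = 0.05) {
  stopifnot(inherits(extrema, "extrema_set"),
            inherits(null, "null_peak_distribution"))
  nv <- null$null_peak_amplitudes
  if (!length(nv)) stop("null distribution is empty")
  amp <- extrema$peak_amplitudes
  if (!length(amp)) {
    out <- data.frame(frame = integer(0), amplitude = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      is_event = logical(0))
    class(out) <- c("event_table", class(out))
    attr(out, "q_threshold") <- q_threshold
    return(out)
  }
  ge <- vapply(amp, function(a) sum(nv >= a), integer(1))
  p <- (1 + ge) / (1 + length(nv))
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(frame = extrema$peak_frames, amplitude = amp,
                    p_value = p, q_value = q, is_event = q <= q_threshold)
  class(out) <- c("event_table", class(out))
  attr(out, "q_threshold") <- q_threshold
  out
}

#' Categorize every frame
#'
#' Frames are partitioned into `event` (significant peaks), `non_event_peak`
#' (remaining RMS peaks), `trough` (local minima), and `other` — the residual
#' pool from which the "random" comparison category samples.
#'
#' @param extrema an `extrema_set`
#' @param events an `event_table`
#' @param T total number of frames
#' @return factor of length T with levels
#'   `c("event", "non_event_peak", "trough", "other")`, class
#'   `frame_categories`
#' @export
categorize_frames <- function(extrema, events, T) {
  cat <- rep("other", T)
  cat[extrema$trough_frames] <- "trough"
  cat[extrema$peak_frames] <- "non_event_peak"
  cat[events$frame[events$is_event]] <- "event"
  structure(factor(cat, levels = c("event", "non_event_peak", "trough", "other")),
            class = c("frame_categories", "factor"))
}

# Mean co-fluctuation pattern over a set of frames, in edge-vector space.
mean_pattern_vec <- function(ets, frames) {
  if (length(frames) == 1L) ets$values[, frames] else rowMeans(ets$values[, frames, drop = FALSE])
}

#' How well does each frame category reconstruct static FC?
#'
#' The events category uses all its frames once (its mean pattern is fixed).
#' Every other category is repeatedly subsampled (without replacement) to the
#' same number of frames as there are events; each subsample's mean pattern is
#' correlated (Pearson, upper triangle) with static FC. Categories smaller
#' than the event count are sampled with replacement and flagged.
#'
#' @param ets an `edge_ts`
#' @param categories a `frame_categories` factor
#' @param fc the static `fc_matrix`
#' @param n_repetitions subsampling repetitions (default 100)
#' @param seed integer seed
#' @return data.frame of class `similarity_report`: `category`,
#'   `mean_similarity`, `sd_similarity`, `n_frames_in_category`,
#'   `sampled_with_replacement`; attributes `n_repetitions`,
#'   `frames_per_sample`
#' @export
reconstruct_fc_similarity <- function(ets, categories, fc,
                                      n_repetitions = 100L, seed = 1L) {
  stopifnot(inherits(ets, "edge_ts"))
  ev_frames <- which(categories == "event")
  if (!length(ev_frames)) stop("no event frames; nothing to compare against")
  k <- length(ev_frames)
  fc_vec <- upper_vec(unclass(fc))
  sim_of <- function(frames) stats::cor(mean_pattern_vec(ets, frames), fc_vec)
  rows <- list()
  with_seed(seed, {
    for (catg in levels(categories)) {
      frames <- which(categories == catg)
      if (!length(frames)) {
        rows[[catg]] <- data.frame(category = catg, mean_similarity = NA_real_,
                                   sd_similarity = NA_real_,
                                   n_frames_in_category = 0L,
                                   sampled_with_replacement = FALSE)
        next
      }
      if (catg == "event") {
        s <- sim_of(frames)
        rows[[catg]] <- data.frame(category = catg, mean_similarity = s,
                                   sd_similarity = 0,
                                   n_frames_in_category = k,
                                   sampled_with_replacement = FALSE)
        next
      }
      replace <- length(frames) < k
      sims <- vapply(seq_len(n_repetitions), function(r) {
        sim_of(sample(frames, k, replace = replace))
      }, numeric(1))
      rows[[catg]] <- data.frame(category = catg,
                                 mean_similarity = mean(sims),
                                 sd_similarity = stats::sd(sims),
                                 n_frames_in_category = length(frames),
                                 sampled_with_replacement = replace)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_repetitions") <- n_repetitions
  attr(out, "frames_per_sample") <- k
  class(out) <- c("similarity_report", class(out))
  out
}

#' Bin frames by RMS amplitude and score each bin against static FC
#'
#' `all_frames` mode assigns every frame to one of `n_bins` equal-count RMS
#' quantile bins; `peak_binning` bins only RMS peak frames. Each bin reports
#' the Pearson similarity of its mean co-fluctuation pattern to static FC and
#' the temporal dispersion of its members — the mean gap between consecutive
#' sampled frame indices, normalized by T (small dispersion = temporally
#' clumped frames, the serial-correlation artifact that makes the extreme
#' all-frames bins misleading).
#'
#' @param ets an `edge_ts`
#' @param rms the matching `rms_series`
#' @param extrema an `extrema_set` (used by `peak_binning`)
#' @param n_bins number of amplitude bins (>= 2)
#' @param mode `"all_frames"` or `"peak_binning"`
#' @return data.frame of class `binning_report`: `bin` (1 = lowest RMS),
#'   `n_frames`, `similarity`, `temporal_dispersion`, `merged`
#' @export
bin_frames_by_amplitude <- function(ets, rms, extrema, n_bins = 10L,
                                    mode = c("all_frames", "peak_binning")) {
  mode <- match.arg(mode)
  if (n_bins < 2) stop("n_bins must be >= 2")
  frames <- if (mode == "all_frames") seq_len(ets$T) else extrema$peak_frames
  if (length(frames) < n_bins) {
    stop("fewer frames (", length(frames), ") than bins (", n_bins, ")")
  }
  amp <- as.numeric(rms)[frames]
  # rank with deterministic tie-breaking: equal-count bins, never empty
  bin <- ceiling(rank(amp, ties.method = "first") * n_bins / length(frames))
  fc_vec <- rowSums(ets$values) / (ets$T - 1)
  rows <- lapply(seq_len(n_bins), function(b) {
    fr <- sort(frames[bin == b])
    disp <- if (length(fr) > 1) mean(diff(fr)) / ets$T else NA_real_
    data.frame(bin = b, n_frames = length(fr),
               similarity = stats::cor(mean_pattern_vec(ets, fr), fc_vec),
               temporal_dispersion = disp, merged = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  class(out) <- c("binning_report", class(out))
  out
}
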