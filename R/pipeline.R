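# End-to-end pipeline driver: per-subject edge time series and event
# detection, aggregation of event patterns across subjects, hierarchical
# clustering, bipartition + nulls per centroid, coupling, and a manifest with
# enough provenance to reproduce every artifact.

pkg_version <- function() as.character(utils::packageVersion("cofluct"))

# jsonlite may simplify a homogeneous record list to a data.frame; treat both
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
extract_record <- function(x, i) {
  if (is.data.frame(x)) as.list(x[i, , drop = FALSE]) else x[[i]]
}

#' Run the full analysis pipeline
#'
#' Stages per subject: standardize, edge time series, RMS, circular-shift
#' null, event detection, frame categories, FC-similarity report, coupling.
#' Event patterns are then aggregated across subjects, clustered
#' hierarchically with Lin's concordance, and each centroid at the configured
#' hierarchy level is tested for induced structural modularity against the
#' independent and geometry-preserving nulls. Every intermediate artifact is
#' written under `config$out_dir`; a manifest JSON records versions, seeds,
#' parameters, and stage outputs. Any stage failure aborts with the stage
#' name; artifacts already written are retained.
#'
#' @param config an [analysis_config()]
#' @return the manifest, invisibly also written to
#'   `file.path(config$out_dir, "manifest.json")`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (!length(config$timeseries)) stop("config$timeseries must list >= 1 subject")
  if (is.null(config$connectome)) stop("config$connectome is required")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = pkg_version(),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = unclass(config), stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  w <- stage("load_connectome", load_dense_matrix(config$connectome))
  sc <- stage("load_connectome", structural_connectome(w))
  coords <- NULL
  if (!is.null(config$node_metadata)) {
    meta <- stage("load_metadata", read_node_metadata(config$node_metadata))
    cc <- intersect(c("x", "y", "z"), names(meta))
    coords <- as.matrix(meta[, cc, drop = FALSE])
  }

  n_subj <- length(config$timeseries)
  patterns <- list()
  pattern_subjects <- character(0)
  per_subject <- list()
  for (s in seq_len(n_subj)) {
    sid <- sprintf("subject%02d", s)
    sdir <- file.path(out, sid)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    ts_raw <- stage(paste0(sid, ":load"), {
      parcel_ts(load_dense_matrix(config$timeseries[s]))
    })
    zts <- stage(paste0(sid, ":standardize"), standardize_timeseries(ts_raw))
    ets <- stage(paste0(sid, ":ets"), compute_edge_timeseries(zts))
    fc <- compute_static_fc(zts)
    rms <- compute_rms(ets)
    null <- stage(paste0(sid, ":null"), build_null_peak_distribution(
      zts, n_runs = config$n_runs,
      seed = derive_seed(config$seed, paste0("null-", sid))))
    extrema <- find_local_extrema(rms)
    events <- detect_events(extrema, null, q_threshold = config$q_threshold)
    cats <- categorize_frames(extrema, events, zts$T)
    ev_frames <- events$frame[events$is_event]
    sim <- if (length(ev_frames)) {
      reconstruct_fc_similarity(ets, cats, fc,
                                n_repetitions = config$n_repetitions,
                                seed = derive_seed(config$seed, paste0("sim-", sid)))
    } else {
      NULL
    }
    coup <- stage(paste0(sid, ":coupling"), coupling_timeseries(ets, sc, rms))

    write_dense_matrix(fc, file.path(sdir, "fc.tsv"))
    data.table::fwrite(cbind(events, frame0 = events$frame - 1L),
                       file.path(sdir, "events.tsv"), sep = "\t")
    data.table::fwrite(
      data.frame(frame = seq_len(zts$T) - 1L, rms = as.numeric(rms),
                 category = as.character(cats)),
      file.path(sdir, "frame_categories.tsv"), sep = "\t")
    if (!is.null(sim)) {
      data.table::fwrite(sim, file.path(sdir, "fc_similarity.tsv"), sep = "\t")
    }
    data.table::fwrite(coup, file.path(sdir, "coupling.tsv"), sep = "\t")

    for (f in ev_frames) {
      patterns[[length(patterns) + 1L]] <- frame_pattern(ets, f, subject_id = sid)
      pattern_subjects <- c(pattern_subjects, sid)
    }
    per_subject[[sid]] <- list(
      n_frames = zts$T, n_peaks = nrow(events), n_events = length(ev_frames),
      n_troughs = length(extrema$trough_frames),
      outputs = file.path(sid, c("fc.tsv", "events.tsv",
                                 "frame_categories.tsv", "coupling.tsv")))
  }
  manifest$stages$subjects <- per_subject
  manifest$stages$n_events_total <- length(patterns)

  if (length(patterns) >= 2) {
    ensemble <- pattern_ensemble(patterns, pattern_subjects)
    cm <- stage("concordance", concordance_matrix(ensemble))
    hier <- stage("clustering", hierarchical_cluster_events(
      cm, n_iter = config$n_iter, n_perm = config$n_perm,
      alpha = config$alpha, seed = derive_seed(config$seed, "cluster")))
    lvl <- min(config$centroid_level, hier$depth)
    assignment <- hier$levels[[lvl]]
    cents <- compute_centroids(ensemble, assignment)
    cdir <- file.path(out, "clusters")
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(
      data.frame(pattern_id = seq_along(assignment) - 1L,
                 subject_id = pattern_subjects,
                 do.call(cbind, stats::setNames(
                   lapply(hier$levels, function(l) l - 1L),
                   paste0("level", seq_len(hier$depth))))),
      file.path(cdir, "members.tsv"), sep = "\t")
    jsonlite::write_json(
      list(levels = lapply(hier$levels, function(l) l - 1L),
           q_contributions = hier$q_contributions,
           Q_levels = hier$Q_levels,
           parent_map = lapply(hier$parent_map, function(p) p - 1L),
           nodes = hier$nodes),
      file.path(cdir, "hierarchy.json"), digits = NA, null = "null")
    bip_results <- list()
    for (c_id in seq_along(cents$centroids)) {
      write_dense_matrix(unclass(cents$centroids[[c_id]]),
                         file.path(cdir, sprintf("centroid_%02d.tsv", c_id)))
      res <- stage(paste0("bipartition-", c_id), gamma_sweep(
        cents$centroids[[c_id]], sc,
        coords %||% layout_coordinates(sc$N, "ring"),
        gammas = config$gammas, n_iter = config$n_iter,
        n_perm = config$n_perm,
        seed = derive_seed(config$seed, paste0("bip", c_id)),
        geometry_strategy = config$geometry_strategy))
      bip_results[[c_id]] <- lapply(res, function(r) {
        if (!r$valid) return(list(gamma = r$gamma, valid = FALSE,
                                  reason = r$reason))
        list(gamma = r$gamma, valid = TRUE,
             n_plus = r$bipartition$n_plus, n_minus = r$bipartition$n_minus,
             Q_induced = r$independent$Q_induced,
             p_independent = r$independent$p_value,
             p_geometry = r$geometry$p_value)
      })
      valid1 <- Filter(function(r) r$valid, res)
      if (length(valid1)) {
        bp <- valid1[[1]]$bipartition
        data.table::fwrite(
          data.frame(node_id = seq_len(sc$N) - 1L, label = bp$labels),
          file.path(cdir, sprintf("bipartition_%02d.tsv", c_id)), sep = "\t")
      }
    }
    jsonlite::write_json(bip_results, file.path(cdir, "induced_modularity.json"),
                         digits = NA, auto_unbox = TRUE, null = "null")
    manifest$stages$clustering <- list(
      depth = hier$depth, level_used = lvl,
      n_clusters = max(assignment),
      member_fraction = cents$member_fraction,
      outputs = file.path("clusters",
                          c("members.tsv", "hierarchy.json",
                            "induced_modularity.json")))
  } else {
    manifest$stages$clustering <- list(
      skipped = TRUE,
      reason = "fewer than 2 events aggregated across subjects")
  }

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' Reads the intermediates a [run_pipeline()] call wrote and produces three
#' summary tables: per-category FC similarity per subject, the cluster
#' summary (counts and member fractions per hierarchy level used), and the
#' induced-modularity table (Q_induced and p-values per centroid and gamma).
#' With zero detected events the report states so and marks downstream
#' tables not applicable.
#'
#' @param out_dir the pipeline output directory containing `manifest.json`
#' @return list of class `run_report` with `n_events_total`, `fc_similarity`,
#'   `clusters`, `induced_modularity` (the latter two `NULL` when not
#'   applicable); tables are also written as TSV under `out_dir`
#' @export
write_report <- function(out_dir) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("missing manifest: ", manifest_path)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  subj <- names(manifest$stages$subjects)
  sims <- list()
  for (sid in subj) {
    p <- file.path(out_dir, sid, "fc_similarity.tsv")
    if (file.exists(p)) {
      df <- data.table::fread(p, data.table = FALSE)
      df$subject_id <- sid
      sims[[sid]] <- df
    }
  }
  fc_similarity <- if (length(sims)) do.call(rbind, sims) else NULL
  n_events <- manifest$stages$n_events_total
  clusters <- induced <- NULL
  if (isTRUE(manifest$stages$clustering$skipped) || n_events == 0) {
    message("report: zero/insufficient events; cluster and modularity tables ",
            "not applicable")
  } else {
    members <- data.table::fread(file.path(out_dir, "clusters", "members.tsv"),
                                 data.table = FALSE)
    lvl <- manifest$stages$clustering$level_used
    lab <- members[[paste0("level", lvl)]]
    counts <- as.data.frame(table(lab), stringsAsFactors = FALSE)
    names(counts) <- c("cluster", "member_count")
    counts$member_fraction <- counts$member_count / sum(counts$member_count)
    clusters <- counts
    ind <- jsonlite::read_json(file.path(out_dir, "clusters",
                                         "induced_modularity.json"),
                               simplifyVector = TRUE)
    rows <- list()
    for (c_id in seq_along(ind)) {
      df <- data.table::rbindlist(
        lapply(seq_len(nrow_or_len(ind[[c_id]])), function(i) {
          as.list(extract_record(ind[[c_id]], i))
        }), fill = TRUE)
      df$cluster <- c_id - 1L
      rows[[c_id]] <- df
    }
    induced <- as.data.frame(data.table::rbindlist(rows, fill = TRUE))
  }
  if (!is.null(fc_similarity)) {
    data.table::fwrite(fc_similarity,
                       file.path(out_dir, "report_fc_similarity.tsv"), sep = "\t")
  }
  if (!is.null(clusters)) {
    data.table::fwrite(clusters, file.path(out_dir, "report_clusters.tsv"),
                       sep = "\t")
  }
  if (!is.null(induced)) {
    data.table::fwrite(induced,
                       file.path(out_dir, "report_induced_modularity.tsv"),
                       sep = "\t")
  }
  structure(list(n_events_total = n_events, fc_similarity = fc_similarity,
                 clusters = clusters, induced_modularity = induced),
            class = "run_report")
}
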