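# File formats: header-less TSV for matrices and tables, JSON for configs,
# ground truth, and manifests. Node and community indices are 0-based on
# disk, 1-based in memory; decimal point is always ".", no locale dependence.

#' Load a dense numeric matrix from delimited text
#'
#' @param path path to a header-less delimited numeric file
#' @param expected_shape optional `c(nrow, ncol)` to enforce
#' @param sep field separator (default tab)
#' @return numeric matrix with a `provenance` attribute (path, md5 checksum,
#'   shape)
#' @export
load_dense_matrix <- function(path, expected_shape = NULL, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = sep, quote = "")
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged file ", path, ": row ", bad, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  dt <- data.table::fread(path, sep = sep, header = FALSE, colClasses = "numeric",
                          data.table = FALSE, showProgress = FALSE)
  m <- as.matrix(dt)
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt, is.numeric, logical(1)))[1]
    stop("non-numeric cells in ", path, " (column ", bad, ")")
  }
  dimnames(m) <- NULL
  if (!is.null(expected_shape) &&
      !identical(dim(m), as.integer(expected_shape))) {
    stop("shape mismatch for ", path, ": got ", nrow(m), " x ", ncol(m),
         ", expected ", expected_shape[1], " x ", expected_shape[2])
  }
  attr(m, "provenance") <- list(path = normalizePath(path),
                                md5 = unname(tools::md5sum(path)),
                                shape = dim(m))
  m
}

#' Write a dense numeric matrix as header-less TSV
#'
#' Values are written with full double precision so write-then-read
#' round-trips to better than 1e-15 relative error.
#'
#' @param m numeric matrix
#' @param path output path
#' @export
write_dense_matrix <- function(m, path) {
  stopifnot(is.matrix(m))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  # %.17g guarantees binary round-trip for doubles
  chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  data.table::fwrite(data.table::as.data.table(chr), path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write node metadata (0-based ids, labels, division, coordinates) as TSV
#' @param coords N x 2 (or N x 3) coordinate matrix
#' @param path output path
#' @param labels optional parcel labels
#' @param division optional anatomical division per node
#' @export
write_node_metadata <- function(coords, path, labels = NULL, division = NULL) {
  n <- nrow(coords)
  df <- data.frame(node_id = seq_len(n) - 1L,
                   label = labels %||% paste0("parcel_", seq_len(n) - 1L),
                   division = division %||% rep("unknown", n))
  df <- cbind(df, as.data.frame(coords))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read node metadata written by [write_node_metadata()]
#' @param path TSV path
#' @return data.frame with unique `node_id`s and coordinate columns
#' @export
read_node_metadata <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (anyDuplicated(df$node_id)) stop("duplicate node_id in ", path)
  df
}

# Known pipeline configuration keys and their defaults.
analysis_config_defaults <- function() {
  list(
    timeseries = character(0), # one TSV path per subject (N x T)
    connectome = NULL,         # N x N TSV path
    node_metadata = NULL,      # node metadata TSV path
    out_dir = "cofluct_out",
    n_runs = 100L, q_threshold = 0.05,
    n_repetitions = 100L,
    n_iter = 1000L, n_perm = 1000L, alpha = 0.05,
    gammas = 1.0, geometry_strategy = "rotation",
    centroid_level = 2L,
    seed = 1L
  )
}

#' Build a validated analysis configuration
#'
#' Unknown keys are rejected; the object round-trips through JSON without
#' loss via [write_analysis_config()] / [read_analysis_config()].
#'
#' @param ... named configuration values overriding the defaults (see
#'   `cofluct:::analysis_config_defaults()`)
#' @return list of class `analysis_config`
#' @export
analysis_config <- function(...) {
  defaults <- analysis_config_defaults()
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (k in names(user)) cfg[k] <- list(user[[k]]) # preserves explicit NULLs
  for (k in c("n_runs", "n_repetitions", "n_iter", "n_perm", "centroid_level",
              "seed")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  structure(cfg, class = "analysis_config")
}

#' @rdname analysis_config
#' @param config an `analysis_config`
#' @param path JSON path
#' @export
write_analysis_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$timeseries <- as.character(raw$timeseries %||% character(0))
  do.call(analysis_config, raw)
}

#' Write synthetic ground truth as JSON (0-based frames and node ids)
#' @param truth a [ground_truth()]
#' @param path JSON path
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(module_labels = truth$module_labels - 1L,
         coordinates = unname(as.matrix(truth$node_coordinates)),
         event_frames = truth$event_frames - 1L,
         event_modes = if (is.null(truth$event_modes)) NULL else
           unname(truth$event_modes)),
    path, digits = NA, null = "null")
  invisible(path)
}

#' Write a synthetic dataset (connectome, time series, truth, config) to a
#' directory
#' @param data result of [simulate_dataset()]
#' @param dir output directory
#' @return invisibly, the paths written
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    connectome = file.path(dir, "connectome.tsv"),
    timeseries = file.path(dir, "timeseries.tsv"),
    truth = file.path(dir, "ground_truth.json"),
    config = file.path(dir, "config.json"),
    nodes = file.path(dir, "nodes.tsv")
  )
  write_dense_matrix(data$sc$weights, paths$connectome)
  write_dense_matrix(data$ts$values, paths$timeseries)
  write_ground_truth(data$truth, paths$truth)
  jsonlite::write_json(unclass(data$config), paths$config, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_node_metadata(data$truth$node_coordinates, paths$nodes,
                      division = paste0("module_", data$truth$module_labels))
  invisible(paths)
}
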