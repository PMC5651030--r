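# On-disk dataset layout: one directory holding `manifest.json` plus one
# delimited-text matrix per instance per channel (`inst{i}_chan{c}.tsv`,
# 0-based indices). The manifest is the single source of truth for channel
# order, labels, group IDs and ROI count; ROI indices are stored 0-based on
# disk and converted to R's 1-based indexing in memory.

write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
}

read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "numeric"))
}

#' Write a connectome dataset to a directory
#'
#' @param dataset a [connectome_dataset()].
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  assert_that(inherits(dataset, "connectome_dataset"),
              "dataset must be a connectome_dataset")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(dataset$data)
  files <- vector("list", d[1])
  for (i in seq_len(d[1])) {
    row <- character(d[2])
    for (c in seq_len(d[2])) {
      fn <- sprintf("inst%d_chan%d.tsv", i - 1L, c - 1L)
      write_matrix_tsv(matrix(dataset$data[i, c, , ], d[3], d[3]),
                       file.path(path, fn))
      row[c] <- fn
    }
    files[[i]] <- row
  }
  manifest <- list(
    format = "ccnn-dataset-v1",
    n_instances = d[1], n_channels = d[2], n_rois = d[3],
    channel_names = as.list(dataset$channel_names),
    labels = dataset$labels,
    group_ids = as.character(dataset$group_ids),
    roi_names = if (is.null(dataset$roi_names)) NULL
                else as.list(dataset$roi_names),
    modified_roi_ids = if (is.null(dataset$modified_roi_ids)) NULL
                       else dataset$modified_roi_ids - 1L,  # 0-based on disk
    params = dataset$params,
    files = files
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a connectome dataset from a directory
#'
#' Channels are read in manifest order regardless of file listing order;
#' missing files or count mismatches raise a schema error naming the
#' offending entry.
#'
#' @param path dataset directory containing `manifest.json`.
#' @return a [connectome_dataset()].
#' @export
read_dataset <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  assert_that(file.exists(mf_path), "manifest not found: ", mf_path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  for (field in c("n_instances", "n_channels", "n_rois", "labels", "files")) {
    assert_that(!is.null(mf[[field]]), "manifest field missing: ", field)
  }
  n_inst <- mf$n_instances; n_chan <- mf$n_channels; n <- mf$n_rois
  assert_that(length(mf$labels) == n_inst,
              "manifest declares ", n_inst, " instances but lists ",
              length(mf$labels), " labels")
  files <- mf$files
  if (is.data.frame(files)) files <- as.matrix(files)
  if (is.list(files)) files <- do.call(rbind, files)
  files <- matrix(as.character(files), n_inst, n_chan)
  assert_that(nrow(files) == n_inst && ncol(files) == n_chan,
              "manifest files table must be instances x channels")
  data <- array(0, dim = c(n_inst, n_chan, n, n))
  for (i in seq_len(n_inst)) {
    for (c in seq_len(n_chan)) {
      fp <- file.path(path, files[i, c])
      assert_that(file.exists(fp), "matrix file missing: ", files[i, c])
      m <- read_matrix_tsv(fp)
      assert_that(all(dim(m) == c(n, n)),
                  "matrix file ", files[i, c], " is ", nrow(m), "x", ncol(m),
                  " but manifest declares ", n, "x", n)
      assert_that(is_symmetric_tol(m, 1e-6),
                  "matrix file ", files[i, c], " is asymmetric beyond tolerance")
      data[i, c, , ] <- m
    }
  }
  connectome_dataset(
    data, labels = mf$labels,
    group_ids = if (is.null(mf$group_ids)) NULL else mf$group_ids,
    channel_names = unlist(mf$channel_names),
    roi_names = if (is.null(mf$roi_names)) NULL else unlist(mf$roi_names),
    modified_roi_ids = if (is.null(mf$modified_roi_ids)) NULL
                       else unlist(mf$modified_roi_ids) + 1L,
    params = if (is.null(mf$params)) list() else mf$params,
    tol = 1e-6
  )
}

#' Save a model to a directory
#'
#' Writes `config.json` (architecture, optimizer settings, class labels,
#' standardization statistics and training log) and one delimited-text file
#' per layer parameter.
#'
#' @param model a `ccnn_model`.
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ccnn_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    config = unclass(model$config),
    classes = model$classes,
    trained = model$trained,
    training_log = model$training_log,
    stats = model$stats,
    weight_files = as.list(paste0(names(model$weights), ".tsv"))
  )
  names(meta$weight_files) <- names(model$weights)
  jsonlite::write_json(meta, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  for (nm in names(model$weights)) {
    w <- model$weights[[nm]]
    if (!is.matrix(w)) w <- matrix(w, nrow = 1L)
    write_matrix_tsv(w, file.path(path, paste0(nm, ".tsv")))
  }
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path model directory.
#' @return a `ccnn_model`.
#' @export
load_model <- function(path) {
  meta_path <- file.path(path, "config.json")
  assert_that(file.exists(meta_path), "model config not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cfg <- meta$config
  config <- model_config(
    kind = cfg$kind, n_rois = cfg$n_rois, n_channels = cfg$n_channels,
    conv1_filters = cfg$conv1_filters, conv2_filters = cfg$conv2_filters,
    hidden_units = cfg$hidden_units, dense_units = cfg$dense_units,
    n_classes = cfg$n_classes, keep_prob = cfg$keep_prob,
    optimizer = cfg$optimizer, learning_rate = cfg$learning_rate,
    epochs = cfg$epochs, batch_size = cfg$batch_size, seed = cfg$seed,
    standardize = cfg$standardize, patience = cfg$patience,
    min_delta = cfg$min_delta)
  model <- build_model(config)
  for (nm in names(meta$weight_files)) {
    w <- read_matrix_tsv(file.path(path, meta$weight_files[[nm]]))
    if (startsWith(nm, "b")) w <- as.vector(w)
    assert_that(length(w) == length(model$weights[[nm]]),
                "weight file for ", nm, " has the wrong size")
    if (is.matrix(model$weights[[nm]])) {
      w <- matrix(w, nrow(model$weights[[nm]]), ncol(model$weights[[nm]]))
    }
    model$weights[[nm]] <- w
  }
  model$classes <- meta$classes
  model$trained <- isTRUE(meta$trained)
  model$training_log <- as.numeric(meta$training_log)
  if (!is.null(meta$stats) && length(meta$stats)) {
    model$stats <- list(mean = as.numeric(meta$stats$mean),
                        sd = as.numeric(meta$stats$sd))
  }
  model
}

#' Read ROI time series from delimited text
#'
#' Expects T rows x N columns; an optional single header row carries ROI
#' names (auto-detected: a non-numeric first row is treated as the header).
#'
#' @param path file path.
#' @param sep field separator (default tab; whitespace also accepted).
#' @param sampling_interval TR in seconds, stored on the result.
#' @return a [timeseries_set()].
#' @export
read_timeseries <- function(path, sep = "\t", sampling_interval = 3.0) {
  assert_that(file.exists(path), "time-series file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  tab <- utils::read.table(path, sep = sep, header = has_header)
  m <- as.matrix(tab)
  if (!has_header) colnames(m) <- NULL
  timeseries_set(m, sampling_interval = sampling_interval,
                 roi_names = if (has_header) colnames(tab) else NULL)
}
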