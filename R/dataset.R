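#' Labelled multi-channel connectome dataset
#'
#' Bundles connectivity matrices with class labels and group identifiers into
#' the unit of training and evaluation. Each instance carries one N x N
#' matrix per channel (a channel is one connectivity metric, stacked like a
#' colour channel of an image).
#'
#' @param data numeric 4-d array with dimensions
#'   `instances x channels x n_rois x n_rois`; every `N x N` slice must be
#'   symmetric within `tol`.
#' @param labels integer class label per instance (two or more classes).
#' @param group_ids identifier per instance used for grouped
#'   cross-validation (subject ID for real data). Defaults to one singleton
#'   group per instance, which makes grouped CV coincide with plain k-fold.
#' @param channel_names character vector naming the channels (metric names).
#' @param roi_names optional character vector of length `n_rois`.
#' @param modified_roi_ids optional integer vector of ground-truth modified
#'   ROI indices (1-based) recorded by the simulator.
#' @param params optional list of generator parameters kept as metadata.
#' @param tol symmetry tolerance for each matrix slice.
#'
#' @return An object of class `connectome_dataset`: a list with elements
#'   `data`, `labels`, `group_ids`, `channel_names`, `roi_names`,
#'   `modified_roi_ids`, `params`.
#' @export
connectome_dataset <- function(data, labels, group_ids = NULL,
                               channel_names = NULL, roi_names = NULL,
                               modified_roi_ids = NULL, params = list(),
                               tol = 1e-9) {
  assert_that(is.array(data) && length(dim(data)) == 4L,
              "`data` must be a 4-d array (instances x channels x N x N)")
  d <- dim(data)
  assert_that(d[3] == d[4], "connectivity slices must be square")
  n_inst <- d[1]; n_chan <- d[2]; n_rois <- d[3]
  assert_that(length(labels) == n_inst,
              "length(labels) must equal the instance count (",
              length(labels), " vs ", n_inst, ")")
  labels <- as.integer(labels)
  assert_that(length(unique(labels)) >= 2L || n_inst <= 1L,
              "labels must take at least two distinct classes")
  if (is.null(group_ids)) group_ids <- seq_len(n_inst)
  assert_that(length(group_ids) == n_inst,
              "length(group_ids) must equal the instance count")
  if (is.null(channel_names)) channel_names <- paste0("channel", seq_len(n_chan))
  assert_that(length(channel_names) == n_chan,
              "length(channel_names) must equal the channel count")
  if (!is.null(roi_names)) {
    assert_that(length(roi_names) == n_rois,
                "length(roi_names) must equal n_rois")
  }
  if (!is.null(modified_roi_ids)) {
    modified_roi_ids <- as.integer(modified_roi_ids)
    assert_that(all(modified_roi_ids >= 1L & modified_roi_ids <= n_rois),
                "modified_roi_ids out of range")
  }
  for (i in seq_len(n_inst)) {
    for (c in seq_len(n_chan)) {
      m <- data[i, c, , , drop = TRUE]
      if (n_rois == 1L) m <- matrix(m, 1L, 1L)
      if (!is_symmetric_tol(m, tol)) {
        stop_invalid("matrix of instance ", i, ", channel ", c,
                     " is not symmetric within ", tol)
      }
    }
  }
  structure(
    list(data = data, labels = labels, group_ids = group_ids,
         channel_names = channel_names, roi_names = roi_names,
         modified_roi_ids = modified_roi_ids, params = params),
    class = "connectome_dataset"
  )
}

#' @export
print.connectome_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat("<connectome_dataset> ", d[1], " instances, ", d[2], " channel(s) [",
      paste(x$channel_names, collapse = ", "), "], ", d[3], " ROIs\n", sep = "")
  tab <- table(x$labels)
  cat("  classes: ", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "; ", length(unique(x$group_ids)), " group(s)\n", sep = "")
  if (!is.null(x$modified_roi_ids)) {
    cat("  ground-truth modified ROIs: ",
        paste(x$modified_roi_ids, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of instances, channels and ROIs of a dataset
#' @param dataset a [connectome_dataset()].
#' @return named integer vector with elements `instances`, `channels`, `rois`.
#' @export
dataset_dims <- function(dataset) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  d <- dim(dataset$data)
  c(instances = d[1], channels = d[2], rois = d[3])
}

#' Subset a connectome dataset by instance
#' @param dataset a [connectome_dataset()].
#' @param indices instance indices to keep.
#' @return a `connectome_dataset` with the selected instances.
#' @export
dataset_subset <- function(dataset, indices) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  connectome_dataset(
    dataset$data[indices, , , , drop = FALSE],
    labels = dataset$labels[indices],
    group_ids = dataset$group_ids[indices],
    channel_names = dataset$channel_names,
    roi_names = dataset$roi_names,
    modified_roi_ids = dataset$modified_roi_ids,
    params = dataset$params
  )
}

#' Concatenate the channels of several datasets describing the same instances
#'
#' Merges per-metric datasets (for example a DTW-distance dataset and a
#' warping-path-length dataset over the same measurements) into one
#' multi-channel dataset, the input format of the multi-channel CCNN.
#'
#' @param ... two or more [connectome_dataset()] objects with identical
#'   instance count, labels, group IDs and ROI count.
#' @return a `connectome_dataset` whose channels are the inputs' channels
#'   concatenated in argument order.
#' @export
merge_channels <- function(...) {
  parts <- list(...)
  assert_that(length(parts) >= 1L, "merge_channels() needs at least one dataset")
  for (p in parts) {
    assert_that(inherits(p, "connectome_dataset"),
                "all arguments must be connectome_dataset objects")
  }
  if (length(parts) == 1L) return(parts[[1L]])
  ref <- parts[[1L]]
  dref <- dim(ref$data)
  for (p in parts[-1L]) {
    dp <- dim(p$data)
    assert_that(dp[1] == dref[1], "instance counts differ between datasets")
    assert_that(dp[3] == dref[3], "ROI counts differ between datasets")
    assert_that(identical(as.integer(p$labels), as.integer(ref$labels)),
                "labels differ between datasets")
    assert_that(identical(as.character(p$group_ids), as.character(ref$group_ids)),
                "group_ids differ between datasets")
  }
  n_chan <- sum(vapply(parts, function(p) dim(p$data)[2], integer(1)))
  out <- array(0, dim = c(dref[1], n_chan, dref[3], dref[4]))
  at <- 0L
  for (p in parts) {
    nc <- dim(p$data)[2]
    out[, at + seq_len(nc), , ] <- p$data
    at <- at + nc
  }
  connectome_dataset(
    out, labels = ref$labels, group_ids = ref$group_ids,
    channel_names = unlist(lapply(parts, `[[`, "channel_names")),
    roi_names = ref$roi_names,
    modified_roi_ids = ref$modified_roi_ids,
    params = ref$params
  )
}
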