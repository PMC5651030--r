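#' Summarize first-layer CCNN weights into ROI/filter importance
#'
#' The first convolutional layer weights one full connectivity fingerprint
#' per ROI, so summing the absolute weights over the 64 filters yields a
#' per-ROI importance score: high values mark ROIs that influence most
#' filters. Summing over ROIs instead gives a per-filter score. Profiles are
#' reported per channel, never pooled silently. Note that ROIs with small
#' first-layer mass can still matter — filter outputs are re-weighted in the
#' second layer — so these profiles are a first-layer summary, not a full
#' attribution.
#'
#' @param model a trained `ccnn_model` of kind `"ccnn"`.
#' @return object of class `importance_profile`: list with `per_roi`
#'   (channels x N matrix of summed absolute weights), `per_filter`
#'   (channels x filters), `roi_ranking` (list per channel of ROI indices by
#'   descending importance) and `channel_names`.
#' @export
roi_importance <- function(model) {
  stopifnot(inherits(model, "ccnn_model"))
  assert_that(model$config$kind == "ccnn",
              "ROI importance is defined for CCNN models only (got ",
              model$config$kind, ")")
  assert_that(isTRUE(model$trained), "model must be trained")
  cfg <- model$config
  n <- cfg$n_rois; n_chan <- cfg$n_channels; f1 <- cfg$conv1_filters
  w1 <- abs(model$weights$W1)               # f1 x (C*N), channel-major cols
  per_roi <- matrix(0, n_chan, n)
  per_filter <- matrix(0, n_chan, f1)
  for (c in seq_len(n_chan)) {
    block <- w1[, (c - 1L) * n + seq_len(n), drop = FALSE]
    per_roi[c, ] <- colSums(block)
    per_filter[c, ] <- rowSums(block)
  }
  structure(list(
    per_roi = per_roi, per_filter = per_filter,
    roi_ranking = lapply(seq_len(n_chan),
                         function(c) order(per_roi[c, ], decreasing = TRUE)),
    channel_names = paste0("channel", seq_len(n_chan))
  ), class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, ...) {
  cat("<importance_profile> ", nrow(x$per_roi), " channel(s) x ",
      ncol(x$per_roi), " ROIs; top ROIs per channel:\n", sep = "")
  for (c in seq_len(nrow(x$per_roi))) {
    cat("  [", c, "] ", paste(utils::head(x$roi_ranking[[c]], 5L),
                              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Count recovered ground-truth ROIs among the top-ranked ones
#'
#' On simulated data the ROIs whose fingerprints were replaced are known;
#' this scores how many of them appear among the `top_k` ROIs with the
#' largest summed absolute first-layer weight.
#'
#' @param profile an [roi_importance()] result.
#' @param true_roi_ids ground-truth modified ROI indices (1-based).
#' @param top_k how many top-ranked ROIs to inspect.
#' @param channel channel index to use; `NULL` (default) pools channels by
#'   summing their per-ROI importances before ranking.
#' @return integer: size of the overlap between the top `top_k` ranked ROIs
#'   and `true_roi_ids`.
#' @export
recovery_score <- function(profile, true_roi_ids, top_k, channel = NULL) {
  stopifnot(inherits(profile, "importance_profile"))
  n <- ncol(profile$per_roi)
  assert_that(is_count(top_k), "top_k must be a positive integer")
  assert_that(top_k <= n, "top_k (", top_k, ") exceeds the ROI count (", n, ")")
  imp <- if (is.null(channel)) {
    colSums(profile$per_roi)
  } else {
    assert_that(is_count(channel) && channel <= nrow(profile$per_roi),
                "invalid channel index")
    profile$per_roi[channel, ]
  }
  ranking <- order(imp, decreasing = TRUE)
  length(intersect(ranking[seq_len(top_k)], as.integer(true_roi_ids)))
}
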