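#' ROI time-series container
#'
#' Holds the averaged BOLD signal of every ROI for one measurement, the raw
#' input to the connectivity metrics.
#'
#' @param signals numeric T x N matrix (time points x ROIs), no missing
#'   values, T >= 2.
#' @param sampling_interval sampling interval (TR) in seconds; default 3.0.
#' @param roi_names optional column names for the ROIs.
#' @return object of class `timeseries_set`.
#' @export
timeseries_set <- function(signals, sampling_interval = 3.0, roi_names = NULL) {
  signals <- as.matrix(signals)
  assert_that(is.numeric(signals) && nrow(signals) >= 2L,
              "signals must be a numeric matrix with at least 2 time points")
  assert_that(!anyNA(signals), "signals must not contain missing values")
  if (!is.null(roi_names)) {
    assert_that(length(roi_names) == ncol(signals),
                "roi_names must have one name per ROI")
    colnames(signals) <- roi_names
  }
  structure(list(signals = signals,
                 sampling_interval = as.numeric(sampling_interval),
                 roi_names = colnames(signals)),
            class = "timeseries_set")
}

#' @export
print.timeseries_set <- function(x, ...) {
  cat("<timeseries_set> ", nrow(x$signals), " time points x ",
      ncol(x$signals), " ROIs (TR = ", x$sampling_interval, " s)\n", sep = "")
  invisible(x)
}

#' DTW parameters
#'
#' @param window_radius Sakoe-Chiba band half-width in samples; alignment is
#'   restricted to |i - j| <= window_radius. `NULL` (default) resolves to
#'   `ceiling(T / 10)` at call time; `T - 1` removes the constraint.
#' @param local_cost pointwise cost: `"absolute"` (|x_i - y_j|, default) or
#'   `"squared"`.
#' @param znormalize z-score each series before alignment (default TRUE), so
#'   the distance reflects shape rather than amplitude.
#' @return object of class `dtw_params`.
#' @export
dtw_params <- function(window_radius = NULL,
                       local_cost = c("absolute", "squared"),
                       znormalize = TRUE) {
  local_cost <- match.arg(local_cost)
  if (!is.null(window_radius)) {
    assert_that(is_count(window_radius, min = 0L),
                "window_radius must be a non-negative integer")
    window_radius <- as.integer(window_radius)
  }
  structure(list(window_radius = window_radius, local_cost = local_cost,
                 znormalize = isTRUE(znormalize)),
            class = "dtw_params")
}

resolve_radius <- function(params, t) {
  r <- params$window_radius
  if (is.null(r)) r <- as.integer(ceiling(t / 10))
  assert_that(r <= t - 1L, "window_radius must be <= T - 1 (T = ", t, ")")
  r
}

znorm <- function(v, what = "series") {
  s <- sd(v)
  if (!is.finite(s) || s == 0) {
    stop_invalid("cannot z-normalize a constant ", what)
  }
  (v - mean(v)) / s
}

#' Dynamic Time Warping between two equal-length series
#'
#' Computes the accumulated optimal alignment cost under the step set
#' \{(1,0), (0,1), (1,1)\} inside a Sakoe-Chiba band, by dynamic
#' programming, and recovers one optimal warping path by backtracking with
#' diagonal-preferred tie-breaking. The DTW distance measures connectivity
#' strength between two ROI signals while tolerating local phase shifts; the
#' number of cells of the warping path (its length L, with T <= L <= 2T - 1)
#' measures phase stability: identical-phase signals align along the
#' diagonal (L = T), unstable phase relations force detours (larger L).
#'
#' @param x,y numeric vectors of equal length T.
#' @param params a [dtw_params()] object.
#' @return object of class `dtw_result`: list with `distance`,
#'   `path_length` (raw L) and `relative_path_length` ((L - T) / T).
#' @export
dtw_pair <- function(x, y, params = dtw_params()) {
  assert_that(inherits(params, "dtw_params"), "params must be dtw_params")
  x <- as.numeric(x); y <- as.numeric(y)
  assert_that(length(x) == length(y),
              "series must have equal length (", length(x), " vs ", length(y), ")")
  t <- length(x)
  assert_that(t >= 2L, "series must have at least 2 samples")
  r <- resolve_radius(params, t)
  if (params$znormalize) {
    x <- znorm(x); y <- znorm(y)
  }
  res <- .dtw_core(x, y, r, params$local_cost == "squared")
  structure(list(distance = res$distance,
                 path_length = as.integer(res$path_length),
                 relative_path_length = (res$path_length - t) / t),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat("<dtw_result> distance = ", signif(x$distance, 6),
      ", path length = ", x$path_length,
      " (relative ", signif(x$relative_path_length, 4), ")\n", sep = "")
  invisible(x)
}

#' Pearson correlation connectivity matrix
#'
#' @param ts a [timeseries_set()].
#' @return symmetric N x N matrix with unit diagonal; entry (i, j) is the
#'   Pearson correlation of ROI signals i and j.
#' @export
pearson_matrix <- function(ts) {
  assert_that(inherits(ts, "timeseries_set"), "ts must be a timeseries_set")
  sds <- apply(ts$signals, 2L, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(ts$roi_names)) ts$roi_names[bad] else bad
    stop_invalid("ROI(s) with zero-variance signal: ",
                 paste(nm, collapse = ", "))
  }
  m <- cor(ts$signals)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' DTW distance and warping-path-length connectivity matrices
#'
#' Runs [dtw_pair()] over all unordered ROI pairs. Both outputs are
#' symmetric; the distance matrix has a zero diagonal, and the path-length
#' matrix is reported in relative form (L - T) / T by default, which is 0 on
#' the diagonal.
#'
#' @param ts a [timeseries_set()].
#' @param params a [dtw_params()].
#' @param path_length form of the path-length channel: `"relative"`
#'   ((L - T) / T, default) or `"raw"` (L, with diagonal T).
#' @return list with `distance` and `path_length`, both N x N matrices.
#' @export
dtw_matrices <- function(ts, params = dtw_params(),
                         path_length = c("relative", "raw")) {
  assert_that(inherits(ts, "timeseries_set"), "ts must be a timeseries_set")
  assert_that(inherits(params, "dtw_params"), "params must be dtw_params")
  path_length <- match.arg(path_length)
  sig <- ts$signals
  t <- nrow(sig)
  r <- resolve_radius(params, t)
  if (params$znormalize) {
    sig <- apply(sig, 2L, function(v) znorm(v, "ROI signal"))
  }
  res <- .dtw_all_pairs(sig, r, params$local_cost == "squared")
  pl <- res$path_length
  if (path_length == "relative") pl <- (pl - t) / t
  nm <- ts$roi_names
  if (!is.null(nm)) {
    dimnames(res$distance) <- dimnames(pl) <- list(nm, nm)
  }
  list(distance = res$distance, path_length = pl)
}

#' Build a single-instance connectivity dataset from time series
#'
#' Convenience wrapper mapping one measurement's time series to the
#' requested connectivity channels.
#'
#' @param ts a [timeseries_set()].
#' @param metrics character subset of `c("correlation", "dtw", "path")`.
#' @param params a [dtw_params()] used for the DTW-based metrics.
#' @return named list of N x N matrices, one per requested metric.
#' @export
connectivity_matrices <- function(ts, metrics = c("correlation", "dtw", "path"),
                                  params = dtw_params()) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- list()
  if ("correlation" %in% metrics) out$correlation <- pearson_matrix(ts)
  if (any(c("dtw", "path") %in% metrics)) {
    dm <- dtw_matrices(ts, params)
    if ("dtw" %in% metrics) out$dtw <- dm$distance
    if ("path" %in% metrics) out$path <- dm$path_length
  }
  out
}
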