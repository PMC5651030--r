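#' Generate a synthetic healthy/alternative base connectome pair
#'
#' Produces two distinct correlation-structured connectomes via independent
#' latent-factor draws: each matrix is the Pearson correlation matrix of
#' latent signals built from a small number of shared factors plus
#' idiosyncratic noise. The construction forces symmetry, a unit diagonal,
#' entries in \[-1, 1\] and positive semidefiniteness — the statistical shape
#' of a real resting-state functional connectome. The "alternative" member
#' plays the role of a patient connectome whose ROI fingerprints are grafted
#' onto the healthy one by [replace_roi_fingerprints()].
#'
#' @param n_rois number of ROIs (N >= 2).
#' @param seed integer seed; the output is bitwise-reproducible given the seed.
#' @param n_factors number of shared latent factors; defaults to roughly one
#'   factor per ten ROIs, giving block-structured correlations similar in
#'   spirit to functional networks.
#' @param n_timepoints length of the latent signals the correlations are
#'   computed from.
#' @return object of class `base_connectome_pair`: list with `healthy`,
#'   `alternative` (both N x N) and `n_rois`.
#' @export
generate_base_pair <- function(n_rois, seed = 1L,
                               n_factors = max(2L, round(n_rois / 10)),
                               n_timepoints = max(200L, 2L * n_rois)) {
  assert_that(is_count(n_rois, min = 2L), "n_rois must be an integer >= 2")
  draw <- function() {
    f <- matrix(rnorm(n_timepoints * n_factors), n_timepoints, n_factors)
    loadings <- matrix(rnorm(n_rois * n_factors), n_rois, n_factors)
    signals <- f %*% t(loadings) +
      matrix(rnorm(n_timepoints * n_rois, sd = 1.0), n_timepoints, n_rois)
    m <- cor(signals)
    # exact unit diagonal / symmetry regardless of floating-point round-off
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m
  }
  with_seed(seed, {
    healthy <- draw()
    alternative <- draw()
    structure(
      list(healthy = healthy, alternative = alternative, n_rois = n_rois),
      class = "base_connectome_pair"
    )
  })
}

#' @export
print.base_connectome_pair <- function(x, ...) {
  cat("<base_connectome_pair> ", x$n_rois, " ROIs; mean |healthy - alternative| = ",
      signif(mean(abs(x$healthy - x$alternative)), 3), "\n", sep = "")
  invisible(x)
}

#' Replace the connectivity fingerprints of selected ROIs
#'
#' Grafts the rows and columns of `donor` corresponding to `roi_ids` onto
#' `base`. A ROI's fingerprint is its full row (equivalently column) of
#' connectivity values, so replacing rows and columns jointly keeps the
#' output symmetric; entries at the intersection of two replaced ROIs take
#' the donor values. Diagonal entries remain 1.
#'
#' @param base symmetric N x N matrix to modify.
#' @param donor symmetric N x N matrix supplying the fingerprints.
#' @param roi_ids integer vector of ROI indices (1-based); may be empty.
#' @return N x N symmetric matrix.
#' @export
replace_roi_fingerprints <- function(base, donor, roi_ids) {
  assert_that(is.matrix(base) && is.matrix(donor) &&
                all(dim(base) == dim(donor)) && nrow(base) == ncol(base),
              "base and donor must be square matrices of identical shape")
  n <- nrow(base)
  roi_ids <- as.integer(roi_ids)
  assert_that(all(roi_ids >= 1L & roi_ids <= n) && !anyDuplicated(roi_ids),
              "roi_ids must be unique indices in 1..", n)
  out <- base
  out[roi_ids, ] <- donor[roi_ids, ]
  out[, roi_ids] <- donor[, roi_ids]
  out
}

#' Symmetrized, max-abs-normalized Gaussian noise matrix
#'
#' Draws an i.i.d. standard-Gaussian N x N matrix A, symmetrizes it as
#' S = A + t(A) so that noisy connectomes stay symmetric, and rescales S so
#' its maximum absolute entry is exactly 1. Diagonal entries are 2 * A\[i,i\]
#' before normalization and are deliberately not zeroed. The realized
#' standard deviation of the entries depends on N through the max-abs
#' rescaling (around 0.2 for moderate N; see the package vignette).
#'
#' @param n_rois matrix dimension (N >= 2).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (the caller controls reproducibility).
#' @return symmetric N x N matrix with `max(abs(.)) == 1`.
#' @export
symmetric_normalized_noise <- function(n_rois, seed = NULL) {
  assert_that(is_count(n_rois, min = 2L), "n_rois must be an integer >= 2")
  draw <- function() {
    a <- matrix(rnorm(n_rois * n_rois), n_rois, n_rois)
    s <- a + t(a)
    s / max(abs(s))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Specification of a simulated connectome benchmark dataset
#'
#' @param n_modified_rois how many ROI fingerprints to replace in the
#'   alternative class (the benchmark uses 1, 5 and 10).
#' @param noise_weight multiplier applied to the normalized noise matrix
#'   added to every replica (the benchmark sweeps weights 1..10).
#' @param replicas_per_class noisy replicas per class (default 75, giving a
#'   balanced 150-instance dataset).
#' @param seed integer seed controlling ROI selection and all noise draws.
#' @param modified_roi_ids optional explicit ROI indices (1-based); when
#'   `NULL` they are drawn uniformly without replacement under `seed` at
#'   dataset-generation time.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_modified_rois, noise_weight,
                            replicas_per_class = 75L, seed = 1L,
                            modified_roi_ids = NULL) {
  assert_that(is_count(n_modified_rois, min = 0L),
              "n_modified_rois must be a non-negative integer")
  assert_that(length(noise_weight) == 1L && is.numeric(noise_weight) &&
                noise_weight >= 0, "noise_weight must be a real >= 0")
  assert_that(is_count(replicas_per_class, min = 1L),
              "replicas_per_class must be a positive integer")
  if (!is.null(modified_roi_ids)) {
    modified_roi_ids <- as.integer(modified_roi_ids)
    assert_that(length(modified_roi_ids) == n_modified_rois &&
                  !anyDuplicated(modified_roi_ids),
                "modified_roi_ids must be ", n_modified_rois, " unique indices")
  }
  structure(
    list(n_modified_rois = as.integer(n_modified_rois),
         noise_weight = as.numeric(noise_weight),
         replicas_per_class = as.integer(replicas_per_class),
         seed = as.integer(seed),
         modified_roi_ids = modified_roi_ids),
    class = "simulation_spec"
  )
}

#' Simulate a balanced two-class connectome dataset
#'
#' Builds the benchmark dataset: class 0 instances are the healthy base
#' connectome plus `noise_weight` times a fresh symmetrized
#' max-abs-normalized Gaussian noise matrix; class 1 instances are the
#' modified connectome (healthy with `n_modified_rois` fingerprints replaced
#' from the alternative connectome) plus independent noise of the same kind.
#' Noise is drawn independently per replica; noisy entries are not clipped
#' to \[-1, 1\]. The ground-truth modified ROI indices are recorded in the
#' returned dataset.
#'
#' @param base_pair a [generate_base_pair()] result (or any
#'   `base_connectome_pair`).
#' @param spec a [simulation_spec()].
#' @return a [connectome_dataset()] with `2 * replicas_per_class` instances,
#'   one channel named `"correlation"`, labels 0 (healthy) and 1 (modified),
#'   singleton group IDs, and `modified_roi_ids` metadata.
#' @export
simulate_dataset <- function(base_pair, spec) {
  assert_that(inherits(base_pair, "base_connectome_pair"),
              "base_pair must be a base_connectome_pair")
  assert_that(inherits(spec, "simulation_spec"),
              "spec must be a simulation_spec")
  n <- base_pair$n_rois
  assert_that(spec$n_modified_rois <= n,
              "n_modified_rois cannot exceed n_rois (", n, ")")
  with_seed(spec$seed, {
    roi_ids <- spec$modified_roi_ids
    if (is.null(roi_ids)) {
      roi_ids <- sort(sample.int(n, spec$n_modified_rois))
    }
    modified <- replace_roi_fingerprints(base_pair$healthy,
                                         base_pair$alternative, roi_ids)
    r <- spec$replicas_per_class
    n_inst <- 2L * r
    data <- array(0, dim = c(n_inst, 1L, n, n))
    labels <- integer(n_inst)
    for (i in seq_len(n_inst)) {
      template <- if (i <= r) base_pair$healthy else modified
      labels[i] <- if (i <= r) 0L else 1L
      data[i, 1L, , ] <- template +
        spec$noise_weight * symmetric_normalized_noise(n)
    }
    connectome_dataset(
      data, labels = labels, group_ids = seq_len(n_inst),
      channel_names = "correlation",
      modified_roi_ids = if (length(roi_ids)) roi_ids else NULL,
      params = list(generator = "simulate_dataset",
                    n_rois = n,
                    n_modified_rois = spec$n_modified_rois,
                    noise_weight = spec$noise_weight,
                    replicas_per_class = spec$replicas_per_class,
                    seed = spec$seed)
    )
  })
}
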