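#' Classifier configuration
#'
#' Describes one of the three architectures:
#'
#' * `ccnn` — connectome-convolutional network. Input C x N x N; first
#'   convolution: `conv1_filters` (64) fingerprint filters of shape
#'   C x 1 x N, each sliding over the N rows (a "line-by-line" 1 x N
#'   convolution spanning all channels), giving 64 features per ROI; ReLU;
#'   second convolution: `conv2_filters` (128) filters of shape 64 x N x 1
#'   collapsing the ROI axis to one 128-vector; ReLU; dense layer of
#'   `dense_units` (96) with ReLU and dropout; dense softmax output.
#' * `simple` — flattened upper-triangle features, one sigmoid hidden layer
#'   of `hidden_units` (128), softmax output; trained with plain SGD.
#' * `deep` — flattened features, ReLU hidden layers of `hidden_units` (128)
#'   and `dense_units` (96, with dropout), softmax output; Adam.
#'
#' @param kind `"ccnn"`, `"simple"` or `"deep"`.
#' @param n_rois number of ROIs N.
#' @param n_channels number of connectivity channels C.
#' @param conv1_filters,conv2_filters CCNN filter counts (64 and 128).
#' @param hidden_units width of the first dense hidden layer of the simple
#'   and deep networks (128).
#' @param dense_units width of the last hidden layer of the ccnn and deep
#'   networks (96).
#' @param n_classes number of output classes (softmax head; default 2).
#' @param keep_prob dropout keeping probability for the `dense_units` layer
#'   of the ccnn and deep networks (default 0.6; the simple network uses no
#'   dropout).
#' @param optimizer `"adam"` (default for ccnn/deep) or `"sgd"` (default
#'   for simple).
#' @param learning_rate step size; defaults 1e-3 for Adam, 0.05 for SGD.
#' @param epochs maximum training epochs (default 200; training stops early
#'   when the loss plateaus, see `patience`).
#' @param batch_size minibatch size (default 16).
#' @param seed integer seed controlling initialization, batch shuffling and
#'   dropout; identical seeds give bitwise-identical trained weights.
#' @param standardize z-score matrix entries per channel using training-fold
#'   statistics; default on for multi-channel inputs, where metrics of
#'   different scales (e.g. DTW distance vs path length) are mixed.
#' @param patience epochs without loss improvement before early stopping.
#' @param min_delta minimum decrease of the epoch loss that counts as an
#'   improvement.
#' @return object of class `model_config`.
#' @export
model_config <- function(kind = c("ccnn", "simple", "deep"),
                         n_rois, n_channels = 1L,
                         conv1_filters = 64L, conv2_filters = 128L,
                         hidden_units = 128L, dense_units = 96L,
                         n_classes = 2L, keep_prob = 0.6,
                         optimizer = NULL, learning_rate = NULL,
                         epochs = 200L, batch_size = 16L, seed = 1L,
                         standardize = n_channels > 1L,
                         patience = 15L, min_delta = 1e-4) {
  kind <- match.arg(kind)
  assert_that(is_count(n_rois, min = 2L), "n_rois must be an integer >= 2")
  assert_that(is_count(n_channels), "n_channels must be a positive integer")
  for (nm in c("conv1_filters", "conv2_filters", "hidden_units",
               "dense_units", "n_classes", "epochs", "batch_size")) {
    assert_that(is_count(get(nm)), nm, " must be a positive integer")
  }
  assert_that(n_classes >= 2L, "n_classes must be >= 2")
  assert_that(is.numeric(keep_prob) && keep_prob > 0 && keep_prob <= 1,
              "keep_prob must be in (0, 1]")
  if (is.null(optimizer)) optimizer <- if (kind == "simple") "sgd" else "adam"
  optimizer <- match.arg(optimizer, c("adam", "sgd"))
  if (is.null(learning_rate)) {
    learning_rate <- if (optimizer == "adam") 1e-3 else 0.05
  }
  assert_that(is.numeric(learning_rate) && learning_rate > 0,
              "learning_rate must be positive")
  structure(
    list(kind = kind, n_rois = as.integer(n_rois),
         n_channels = as.integer(n_channels),
         conv1_filters = as.integer(conv1_filters),
         conv2_filters = as.integer(conv2_filters),
         hidden_units = as.integer(hidden_units),
         dense_units = as.integer(dense_units),
         n_classes = as.integer(n_classes),
         keep_prob = as.numeric(keep_prob),
         optimizer = optimizer, learning_rate = as.numeric(learning_rate),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         seed = as.integer(seed), standardize = isTRUE(standardize),
         patience = as.integer(patience), min_delta = as.numeric(min_delta)),
    class = "model_config"
  )
}

#' Closed-form trainable parameter counts
#'
#' For the CCNN with C channels, N ROIs, 64/128 filters, 96 dense units and
#' 2 outputs the weight count is `C*N*64 + N*64*128 + 128*96 + 96*2` with
#' `64 + 128 + 96 + 2 = 290` biases; adding a channel adds only `N*64`
#' weights (< 1% at N = 499). The dense baselines work on
#' `F = C*N*(N-1)/2` flattened features, so a channel nearly doubles them.
#'
#' @param config a [model_config()].
#' @return list with integer-valued `n_weights` and `n_biases`.
#' @export
count_trainable_weights <- function(config) {
  assert_that(inherits(config, "model_config"), "config must be a model_config")
  n <- as.numeric(config$n_rois); c <- as.numeric(config$n_channels)
  f1 <- as.numeric(config$conv1_filters); f2 <- as.numeric(config$conv2_filters)
  h <- as.numeric(config$hidden_units); d <- as.numeric(config$dense_units)
  k <- as.numeric(config$n_classes)
  feat <- c * n * (n - 1) / 2
  switch(config$kind,
    ccnn = list(n_weights = c * n * f1 + n * f1 * f2 + f2 * d + d * k,
                n_biases = f1 + f2 + d + k),
    simple = list(n_weights = feat * h + h * k,
                  n_biases = h + k),
    deep = list(n_weights = feat * h + h * d + d * k,
                n_biases = h + d + k)
  )
}

# row-major strict-upper-triangle linear indices of an n x n matrix
upper_tri_rowmajor <- function(n) {
  idx <- matrix(seq_len(n * n), n, n)
  t(idx)[lower.tri(idx)]
}

#' Flatten a dataset into independent pairwise connectivity features
#'
#' Extracts, per channel, the strict upper triangle of each symmetric
#' connectivity matrix in row-major order and concatenates the channels,
#' giving `F = C * N * (N - 1) / 2` features per instance (124251 for one
#' channel of 499 ROIs). This is the input representation of the dense
#' (simple/deep) baselines.
#'
#' @param dataset a [connectome_dataset()].
#' @param tol symmetry tolerance; an asymmetric slice beyond it is an error.
#' @return numeric matrix, instances x F.
#' @export
flatten_features <- function(dataset, tol = 1e-9) {
  assert_that(inherits(dataset, "connectome_dataset"),
              "dataset must be a connectome_dataset")
  d <- dim(dataset$data)
  n_inst <- d[1]; n_chan <- d[2]; n <- d[3]
  idx <- upper_tri_rowmajor(n)
  f_per_chan <- length(idx)
  out <- matrix(0, n_inst, n_chan * f_per_chan)
  for (i in seq_len(n_inst)) {
    for (c in seq_len(n_chan)) {
      m <- matrix(dataset$data[i, c, , ], n, n)
      if (!is_symmetric_tol(m, tol)) {
        stop_invalid("instance ", i, " channel ", c,
                     " is asymmetric beyond tolerance ", tol)
      }
      out[i, (c - 1L) * f_per_chan + seq_len(f_per_chan)] <- m[idx]
    }
  }
  out
}

# truncated normal (+-2 sd) used for weight init, TF-style
rtruncnorm2 <- function(n, sd) {
  x <- rnorm(n, sd = sd)
  bad <- which(abs(x) > 2 * sd)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), sd = sd)
    bad <- bad[abs(x[bad]) > 2 * sd]
  }
  x
}

# fan-in scaled, capped at 0.05 so that trained first-layer magnitudes are
# dominated by learned structure rather than initialization mass (the weight
# summaries of roi_importance() rely on this)
init_matrix <- function(nrow, ncol) {
  matrix(rtruncnorm2(nrow * ncol, sd = min(0.05, 1 / sqrt(ncol))), nrow, ncol)
}

#' Instantiate an untrained model
#'
#' Allocates all layer weights with seeded truncated-normal initialization
#' (scale 1/sqrt(fan-in), truncated at two standard deviations) and zero
#' biases.
#'
#' @param config a [model_config()].
#' @return object of class `ccnn_model` (untrained).
#' @export
build_model <- function(config) {
  assert_that(inherits(config, "model_config"), "config must be a model_config")
  n <- config$n_rois; c <- config$n_channels
  f1 <- config$conv1_filters; f2 <- config$conv2_filters
  h <- config$hidden_units; d <- config$dense_units; k <- config$n_classes
  feat <- c * n * (n - 1) / 2
  w <- with_seed(derive_seed(config$seed, 1L), {
    switch(config$kind,
      ccnn = list(W1 = init_matrix(f1, c * n), b1 = numeric(f1),
                  W2 = init_matrix(f2, f1 * n), b2 = numeric(f2),
                  W3 = init_matrix(d, f2), b3 = numeric(d),
                  W4 = init_matrix(k, d), b4 = numeric(k)),
      simple = list(W1 = init_matrix(h, feat), b1 = numeric(h),
                    W2 = init_matrix(k, h), b2 = numeric(k)),
      deep = list(W1 = init_matrix(h, feat), b1 = numeric(h),
                  W2 = init_matrix(d, h), b2 = numeric(d),
                  W3 = init_matrix(k, d), b3 = numeric(k))
    )
  })
  structure(
    list(config = config, weights = w, stats = NULL, classes = NULL,
         trained = FALSE, training_log = numeric(0)),
    class = "ccnn_model"
  )
}

#' @export
print.ccnn_model <- function(x, ...) {
  cnt <- count_trainable_weights(x$config)
  cat("<ccnn_model> kind = ", x$config$kind,
      ", N = ", x$config$n_rois, ", C = ", x$config$n_channels,
      "; ", format(cnt$n_weights, big.mark = ","), " weights + ",
      cnt$n_biases, " biases; ",
      if (x$trained) paste0("trained (", length(x$training_log), " epochs)")
      else "untrained", "\n", sep = "")
  invisible(x)
}

#' Count the parameters actually allocated in a model
#'
#' Tallies the elements of the instantiated weight matrices and bias
#' vectors; by construction it must agree with [count_trainable_weights()].
#'
#' @param model a `ccnn_model`.
#' @return list with `n_weights` and `n_biases`.
#' @export
count_model_parameters <- function(model) {
  stopifnot(inherits(model, "ccnn_model"))
  nm <- names(model$weights)
  wt <- nm[startsWith(nm, "W")]
  bs <- nm[startsWith(nm, "b")]
  list(n_weights = sum(vapply(model$weights[wt], length, numeric(1))),
       n_biases = sum(vapply(model$weights[bs], length, numeric(1))))
}
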