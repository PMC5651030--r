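# Training engine. All layers are expressed as dense matrix products so the
# whole forward/backward pass runs through BLAS: the CCNN's fingerprint
# convolutions are, per instance, an N x (C*N) design matrix times the
# filter bank (conv1) and a flattened-feature-map product (conv2).

check_dataset_vs_config <- function(config, dataset) {
  d <- dim(dataset$data)
  assert_that(d[3] == config$n_rois,
              "dataset has ", d[3], " ROIs but config expects ", config$n_rois)
  assert_that(d[2] == config$n_channels,
              "dataset has ", d[2], " channels but config expects ",
              config$n_channels)
}

# per-channel mean/sd over all matrix entries of the given instances
channel_stats <- function(dataset, indices) {
  n_chan <- dim(dataset$data)[2]
  mu <- numeric(n_chan); sigma <- numeric(n_chan)
  for (c in seq_len(n_chan)) {
    v <- as.vector(dataset$data[indices, c, , ])
    mu[c] <- mean(v)
    s <- sd(v)
    sigma[c] <- if (is.finite(s) && s > 0) s else 1
  }
  list(mean = mu, sd = sigma)
}

# CCNN input: one (B*N) x (C*N) matrix of stacked per-instance designs;
# instance n occupies rows (n-1)*N + 1 .. n*N, channel c the columns
# (c-1)*N + 1 .. c*N.
ccnn_design <- function(config, dataset, indices, stats) {
  n <- config$n_rois; n_chan <- config$n_channels
  b <- length(indices)
  a <- matrix(0, b * n, n_chan * n)
  for (pos in seq_along(indices)) {
    rows <- (pos - 1L) * n + seq_len(n)
    for (c in seq_len(n_chan)) {
      m <- matrix(dataset$data[indices[pos], c, , ], n, n)
      if (!is.null(stats)) m <- (m - stats$mean[c]) / stats$sd[c]
      a[rows, (c - 1L) * n + seq_len(n)] <- m
    }
  }
  a
}

# dense-model input: flattened upper-triangle features, standardized per
# channel block with the stored channel stats
dense_design <- function(config, dataset, indices, stats) {
  x <- flatten_features(dataset_subset(dataset, indices))
  if (!is.null(stats)) {
    n <- config$n_rois
    f_per_chan <- n * (n - 1) / 2
    for (c in seq_len(config$n_channels)) {
      cols <- (c - 1L) * f_per_chan + seq_len(f_per_chan)
      x[, cols] <- (x[, cols] - stats$mean[c]) / stats$sd[c]
    }
  }
  x
}

prepare_design <- function(model, dataset, indices) {
  if (model$config$kind == "ccnn") {
    ccnn_design(model$config, dataset, indices, model$stats)
  } else {
    dense_design(model$config, dataset, indices, model$stats)
  }
}

add_bias <- function(z, b) sweep(z, 2L, b, "+")
relu <- function(z) (z > 0) * z

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# reshape helpers between the stacked conv1 map ((B*N) x f1) and the
# per-instance flattened feature rows (B x (f1*N), index (f-1)*N + i)
stack_to_rows <- function(h, n, b, f1) {
  matrix(aperm(array(h, c(n, b, f1)), c(2L, 1L, 3L)), b, n * f1)
}
rows_to_stack <- function(h, n, b, f1) {
  matrix(aperm(array(h, c(b, n, f1)), c(2L, 1L, 3L)), b * n, f1)
}

# Forward pass over a design matrix. `dropout_masks` NULL at inference;
# during training masks are pre-scaled by 1/keep_prob (inverted dropout).
nn_forward <- function(model, design, batch_size_n = NULL, dropout_mask = NULL) {
  cfg <- model$config
  w <- model$weights
  if (cfg$kind == "ccnn") {
    n <- cfg$n_rois
    b <- nrow(design) / n
    z1 <- add_bias(design %*% t(w$W1), w$b1)      # (B*N) x f1
    h1 <- relu(z1)
    h1rows <- stack_to_rows(h1, n, b, cfg$conv1_filters)
    z2 <- add_bias(h1rows %*% t(w$W2), w$b2)      # B x f2
    h2 <- relu(z2)
    z3 <- add_bias(h2 %*% t(w$W3), w$b3)          # B x d
    h3 <- relu(z3)
    h3d <- if (is.null(dropout_mask)) h3 else h3 * dropout_mask
    z4 <- add_bias(h3d %*% t(w$W4), w$b4)         # B x K
    list(p = softmax_rows(z4), z1 = z1, h1rows = h1rows, z2 = z2, h2 = h2,
         z3 = z3, h3 = h3, h3d = h3d, b = b)
  } else if (cfg$kind == "simple") {
    z1 <- add_bias(design %*% t(w$W1), w$b1)
    h1 <- 1 / (1 + exp(-z1))
    z2 <- add_bias(h1 %*% t(w$W2), w$b2)
    list(p = softmax_rows(z2), z1 = z1, h1 = h1)
  } else {
    z1 <- add_bias(design %*% t(w$W1), w$b1)
    h1 <- relu(z1)
    z2 <- add_bias(h1 %*% t(w$W2), w$b2)
    h2 <- relu(z2)
    h2d <- if (is.null(dropout_mask)) h2 else h2 * dropout_mask
    z3 <- add_bias(h2d %*% t(w$W3), w$b3)
    list(p = softmax_rows(z3), z1 = z1, h1 = h1, z2 = z2, h2 = h2, h2d = h2d)
  }
}

# Gradients of the mean softmax cross-entropy w.r.t. every parameter.
# `y` is a B x K one-hot matrix; returns a list shaped like model$weights.
nn_gradients <- function(model, design, fw, y, dropout_mask) {
  cfg <- model$config
  w <- model$weights
  b <- nrow(y)
  dz_out <- (fw$p - y) / b
  if (cfg$kind == "ccnn") {
    n <- cfg$n_rois
    g <- list()
    g$W4 <- t(dz_out) %*% fw$h3d
    g$b4 <- colSums(dz_out)
    dh3 <- dz_out %*% w$W4
    if (!is.null(dropout_mask)) dh3 <- dh3 * dropout_mask
    dz3 <- dh3 * (fw$z3 > 0)
    g$W3 <- t(dz3) %*% fw$h2
    g$b3 <- colSums(dz3)
    dz2 <- (dz3 %*% w$W3) * (fw$z2 > 0)
    g$W2 <- t(dz2) %*% fw$h1rows
    g$b2 <- colSums(dz2)
    dh1rows <- dz2 %*% w$W2
    dz1 <- rows_to_stack(dh1rows, n, b, cfg$conv1_filters) * (fw$z1 > 0)
    g$W1 <- t(dz1) %*% design
    g$b1 <- colSums(dz1)
    g
  } else if (cfg$kind == "simple") {
    g <- list()
    g$W2 <- t(dz_out) %*% fw$h1
    g$b2 <- colSums(dz_out)
    dz1 <- (dz_out %*% w$W2) * fw$h1 * (1 - fw$h1)
    g$W1 <- t(dz1) %*% design
    g$b1 <- colSums(dz1)
    g
  } else {
    g <- list()
    g$W3 <- t(dz_out) %*% fw$h2d
    g$b3 <- colSums(dz_out)
    dh2 <- dz_out %*% w$W3
    if (!is.null(dropout_mask)) dh2 <- dh2 * dropout_mask
    dz2 <- dh2 * (fw$z2 > 0)
    g$W2 <- t(dz2) %*% fw$h1
    g$b2 <- colSums(dz2)
    dz1 <- (dz2 %*% w$W2) * (fw$z1 > 0)
    g$W1 <- t(dz1) %*% design
    g$b1 <- colSums(dz1)
    g
  }
}

make_optimizer_state <- function(weights, optimizer) {
  if (optimizer != "adam") return(NULL)
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

apply_update <- function(weights, grads, state, optimizer, lr) {
  if (optimizer == "sgd") {
    for (nm in names(grads)) weights[[nm]] <- weights[[nm]] - lr * grads[[nm]]
    return(list(weights = weights, state = state))
  }
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}

design_rows <- function(model, design, positions) {
  if (model$config$kind == "ccnn") {
    n <- model$config$n_rois
    rows <- as.vector(vapply(positions, function(p) (p - 1L) * n + seq_len(n),
                             integer(n)))
    design[rows, , drop = FALSE]
  } else {
    design[positions, , drop = FALSE]
  }
}

dropout_layer_width <- function(config) {
  switch(config$kind, ccnn = , deep = config$dense_units, simple = 0L)
}

#' Train a classifier on selected instances
#'
#' Minimizes the softmax cross-entropy with the configured optimizer (Adam
#' for the ccnn/deep networks, plain minibatch SGD for the simple network),
#' with inverted dropout on the last hidden layer of the ccnn/deep networks
#' active only during training. When `config$standardize` is on, per-channel
#' standardization statistics are computed from the training instances only
#' and stored in the model for use at inference. Training is deterministic
#' given `config$seed`, and stops early once the epoch loss has not improved
#' by `min_delta` for `patience` epochs.
#'
#' @param model an untrained (or re-trainable) `ccnn_model` from
#'   [build_model()].
#' @param dataset a [connectome_dataset()].
#' @param train_indices instance indices to train on; must contain at least
#'   two classes.
#' @return the trained `ccnn_model`, with `training_log` holding the mean
#'   cross-entropy per epoch.
#' @export
train_model <- function(model, dataset, train_indices) {
  stopifnot(inherits(model, "ccnn_model"))
  assert_that(inherits(dataset, "connectome_dataset"),
              "dataset must be a connectome_dataset")
  cfg <- model$config
  check_dataset_vs_config(cfg, dataset)
  assert_that(length(train_indices) > 0, "train_indices must be non-empty")
  y_raw <- dataset$labels[train_indices]
  classes <- sort(unique(y_raw))
  assert_that(length(classes) >= 2L,
              "training set contains a single class (", classes[1], ")")
  assert_that(length(classes) <= cfg$n_classes,
              "more classes in training data than config$n_classes")
  model$classes <- classes
  model$stats <- if (cfg$standardize) channel_stats(dataset, train_indices)
                 else NULL
  design <- prepare_design(model, dataset, train_indices)
  b_all <- length(train_indices)
  y_idx <- match(y_raw, classes)
  y_onehot_all <- matrix(0, b_all, cfg$n_classes)
  y_onehot_all[cbind(seq_len(b_all), y_idx)] <- 1

  drop_w <- dropout_layer_width(cfg)
  use_dropout <- drop_w > 0L && cfg$keep_prob < 1

  state <- make_optimizer_state(model$weights, cfg$optimizer)
  log <- numeric(0)
  best <- Inf; stall <- 0L
  with_seed(derive_seed(cfg$seed, 2L), {
    for (epoch in seq_len(cfg$epochs)) {
      order <- sample.int(b_all)
      starts <- seq(1L, b_all, by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        pos <- order[s:min(s + cfg$batch_size - 1L, b_all)]
        bd <- design_rows(model, design, pos)
        by <- y_onehot_all[pos, , drop = FALSE]
        mask <- NULL
        if (use_dropout) {
          mask <- matrix(
            (runif(length(pos) * drop_w) < cfg$keep_prob) / cfg$keep_prob,
            length(pos), drop_w)
        }
        fw <- nn_forward(model, bd, dropout_mask = mask)
        eps <- 1e-12
        loss <- -mean(log(pmax(rowSums(fw$p * by), eps)))
        epoch_loss <- epoch_loss + loss * length(pos)
        g <- nn_gradients(model, bd, fw, by, mask)
        upd <- apply_update(model$weights, g, state, cfg$optimizer,
                            cfg$learning_rate)
        model$weights <- upd$weights
        state <- upd$state
      }
      epoch_loss <- epoch_loss / b_all
      log <- c(log, epoch_loss)
      if (epoch_loss < best - cfg$min_delta) {
        best <- epoch_loss; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  })
  model$training_log <- log
  model$trained <- TRUE
  model
}

#' Class-membership probabilities for selected instances
#'
#' Runs the forward pass with dropout disabled; per-channel standardization
#' reuses the statistics stored at training time.
#'
#' @param model a trained `ccnn_model`.
#' @param dataset a [connectome_dataset()].
#' @param indices instance indices to score (default: all).
#' @return numeric matrix, instances x classes; rows sum to 1. Column names
#'   are the class labels seen in training.
#' @export
predict_proba <- function(model, dataset,
                          indices = seq_len(dim(dataset$data)[1])) {
  stopifnot(inherits(model, "ccnn_model"))
  assert_that(isTRUE(model$trained), "model must be trained first")
  check_dataset_vs_config(model$config, dataset)
  design <- prepare_design(model, dataset, indices)
  fw <- nn_forward(model, design)
  # a K-class head may have more columns than observed classes; renormalize
  full <- fw$p[, seq_along(model$classes), drop = FALSE]
  full <- full / rowSums(full)
  colnames(full) <- as.character(model$classes)
  full
}

#' Hard label predictions
#' @inheritParams predict_proba
#' @return integer vector of predicted class labels.
#' @export
predict_label <- function(model, dataset,
                          indices = seq_len(dim(dataset$data)[1])) {
  p <- predict_proba(model, dataset, indices)
  model$classes[max.col(p, ties.method = "first")]
}
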