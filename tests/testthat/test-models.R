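test_that("closed-form parameter counts reproduce the published sizes", {
  cases <- list(
    list(kind = "ccnn", c = 1L, w = 4132224, b = 290),
    list(kind = "ccnn", c = 2L, w = 4164160, b = 290),
    list(kind = "simple", c = 1L, w = 15904384, b = 130),
    list(kind = "simple", c = 2L, w = 31808512, b = 130),
    list(kind = "deep", c = 1L, w = 15916608, b = 226),
    list(kind = "deep", c = 2L, w = 31820736, b = 226)
  )
  for (cs in cases) {
    cnt <- count_trainable_weights(
      model_config(cs$kind, n_rois = 499, n_channels = cs$c))
    expect_identical(cnt$n_weights, cs$w)
    expect_identical(cnt$n_biases, cs$b)
  }
  cnt <- count_trainable_weights(model_config("ccnn", n_rois = 10))
  expect_identical(cnt$n_weights, 10 * 64 + 10 * 64 * 128 + 128 * 96 + 96 * 2)
  expect_identical(cnt$n_weights, 95040)
})

test_that("instantiated models carry exactly the closed-form parameters", {
  for (kind in c("ccnn", "simple", "deep")) {
    for (nc in list(c(10L, 1L), c(10L, 2L), c(499L, 1L), c(499L, 2L))) {
      cfg <- model_config(kind, n_rois = nc[1], n_channels = nc[2])
      got <- count_model_parameters(build_model(cfg))
      want <- count_trainable_weights(cfg)
      expect_identical(got$n_weights, want$n_weights)
      expect_identical(got$n_biases, want$n_biases)
    }
  }
})

test_that("a channel adds N*64 weights to the CCNN but ~doubles dense nets", {
  w <- function(kind, c) {
    count_trainable_weights(model_config(kind, n_rois = 499,
                                         n_channels = c))$n_weights
  }
  expect_identical(w("ccnn", 2) - w("ccnn", 1), 499 * 64)
  expect_lt((w("ccnn", 2) - w("ccnn", 1)) / w("ccnn", 1), 0.01)
  expect_identical(w("simple", 2) - w("simple", 1), 124251 * 128)
  expect_gt(w("simple", 2) / w("simple", 1), 1.9)
  expect_identical(w("deep", 2) - w("deep", 1), 124251 * 128)
})

test_that("flatten_features extracts the strict upper triangle row-major", {
  m <- matrix(c(1, .2, .3,
                .2, 1, .4,
                .3, .4, 1), 3, 3, byrow = TRUE)
  data <- array(0, c(2, 1, 3, 3))
  data[1, 1, , ] <- m
  data[2, 1, , ] <- diag(3)
  ds <- connectome_dataset(data, labels = c(0, 1))
  x <- flatten_features(ds)
  expect_identical(dim(x), c(2L, 3L))
  expect_identical(x[1, ], c(.2, .3, .4))   # (1,2), (1,3), (2,3)

  d2 <- array(0, c(2, 2, 4, 4))
  d2[, , , ] <- 0
  ds2 <- connectome_dataset(d2, labels = c(0, 1))
  expect_identical(ncol(flatten_features(ds2)), 12L)  # 2 * 4*3/2

  ds$data[2, 1, 1, 3] <- 99   # break symmetry behind the constructor's back
  expect_error(flatten_features(ds), "asymmetric")
})

test_that("a 499-ROI single-channel dataset flattens to 124251 features", {
  data <- array(0, c(2, 1, 499, 499))
  ds <- connectome_dataset(data, labels = c(0, 1))
  expect_identical(ncol(flatten_features(ds)), 124251L)
})

test_that("training fits a separable toy problem and is deterministic", {
  ds <- make_toy_dataset()
  train_idx <- c(1:7, 11:17)
  test_idx <- setdiff(1:20, train_idx)
  for (kind in c("ccnn", "simple", "deep")) {
    cfg <- fast_config(kind, ds, epochs = 150L, seed = 42L)
    m <- train_model(build_model(cfg), ds, train_idx)
    expect_true(m$trained)
    expect_lte(utils::tail(m$training_log, 1), m$training_log[1])
    p <- predict_proba(m, ds, train_idx)
    expect_true(all(abs(rowSums(p) - 1) < 1e-6))
    expect_true(all(p >= 0 & p <= 1))
    acc_train <- mean(predict_label(m, ds, train_idx) == ds$labels[train_idx])
    acc_test <- mean(predict_label(m, ds, test_idx) == ds$labels[test_idx])
    expect_identical(acc_train, 1)
    expect_identical(acc_test, 1)
    # bitwise determinism under the same seed
    m2 <- train_model(build_model(cfg), ds, train_idx)
    expect_identical(m$weights, m2$weights)
  }
})

test_that("duplicated instances get identical probability rows", {
  ds <- make_toy_dataset()
  cfg <- fast_config("ccnn", ds, epochs = 30L, seed = 1L)
  m <- train_model(build_model(cfg), ds, 1:20)
  p <- predict_proba(m, ds, c(3L, 3L, 9L))
  expect_identical(p[1, ], p[2, ])
})

test_that("single-class training sets are rejected", {
  ds <- make_toy_dataset()
  cfg <- fast_config("ccnn", ds)
  expect_error(train_model(build_model(cfg), ds, 1:10), "single class")
  expect_error(train_model(build_model(cfg), ds, integer(0)), "non-empty")
})

test_that("dataset shape must match the model config", {
  ds <- make_toy_dataset()
  cfg <- model_config("ccnn", n_rois = 12)
  expect_error(train_model(build_model(cfg), ds, 1:20), "ROIs")
})

test_that("conv filters are covariant under a joint ROI permutation", {
  # permuting the ROI order of the input together with the conv1 filter
  # columns and the conv2 ROI positions leaves the network output unchanged
  ds <- make_toy_dataset(n_rois = 6L, replicas = 5L)
  cfg <- fast_config("ccnn", ds, epochs = 20L, seed = 9L)
  m <- train_model(build_model(cfg), ds, 1:10)
  n <- 6L; f1 <- cfg$conv1_filters
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  ds_p <- ds
  ds_p$data <- ds$data[, , perm, perm, drop = FALSE]
  m_p <- m
  m_p$weights$W1 <- m$weights$W1[, perm, drop = FALSE]
  w2_cols <- as.vector(outer(perm, (seq_len(f1) - 1L) * n, "+"))
  m_p$weights$W2 <- m$weights$W2[, w2_cols, drop = FALSE]
  expect_equal(predict_proba(m_p, ds_p, 1:10), predict_proba(m, ds, 1:10),
               tolerance = 1e-10)
})
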