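test_that("base connectome pairs are valid correlation structures", {
  pair <- generate_base_pair(4, seed = 0)
  for (m in list(pair$healthy, pair$alternative)) {
    expect_equal(dim(m), c(4, 4))
    expect_lt(max(abs(m - t(m))), 1e-12)
    expect_identical(unname(diag(m)), rep(1, 4))
    expect_true(all(m >= -1 & m <= 1))
  }
  expect_false(identical(pair$healthy, pair$alternative))
})

test_that("a 499-ROI connectome carries 124251 independent pairwise features", {
  pair <- generate_base_pair(499, seed = 1)
  n <- pair$n_rois
  expect_identical(n * (n - 1) / 2, 124251)
  expect_lt(max(abs(pair$healthy - t(pair$healthy))), 1e-12)
})

test_that("base pair generation is deterministic given the seed", {
  expect_identical(generate_base_pair(12, seed = 7),
                   generate_base_pair(12, seed = 7))
  expect_false(identical(generate_base_pair(12, seed = 7)$healthy,
                         generate_base_pair(12, seed = 8)$healthy))
  expect_error(generate_base_pair(1), "n_rois")
})

test_that("fingerprint replacement grafts exactly the selected rows/columns", {
  base <- matrix(0.5, 3, 3); diag(base) <- 1
  donor <- matrix(0.9, 3, 3); diag(donor) <- 1
  out <- replace_roi_fingerprints(base, donor, 1L)
  expect_equal(out[1, 2], 0.9); expect_equal(out[2, 1], 0.9)
  expect_equal(out[1, 3], 0.9); expect_equal(out[3, 1], 0.9)
  expect_equal(out[2, 3], 0.5); expect_equal(out[3, 2], 0.5)
  expect_identical(unname(diag(out)), rep(1, 3))

  pair <- generate_base_pair(20, seed = 5)
  expect_identical(replace_roi_fingerprints(pair$healthy, pair$alternative,
                                            integer(0)),
                   pair$healthy)
  expect_equal(replace_roi_fingerprints(pair$healthy, pair$alternative, 1:20),
               pair$alternative)
  expect_error(replace_roi_fingerprints(pair$healthy, pair$alternative, 21),
               "roi_ids")
  expect_error(replace_roi_fingerprints(pair$healthy,
                                        pair$alternative[1:19, 1:19], 1),
               "shape")
})

test_that("replacement touches only the union of selected rows and columns", {
  pair <- generate_base_pair(15, seed = 9)
  for (m in c(1L, 4L, 7L)) {
    ids <- ccnn:::with_seed(m, sample.int(15, m))
    out <- replace_roi_fingerprints(pair$healthy, pair$alternative, ids)
    diff_idx <- which(out != pair$healthy, arr.ind = TRUE)
    expect_true(all(diff_idx[, 1] %in% ids | diff_idx[, 2] %in% ids))
    expect_lt(max(abs(out - t(out))), 1e-12)
  }
})

test_that("noise matrices are symmetric with max absolute value exactly 1", {
  s <- symmetric_normalized_noise(100, seed = 4)
  expect_identical(max(abs(s)), 1)
  expect_identical(s, t(s))
  # zero-mean construction: empirical mean within 3 standard errors
  sd_entry <- sd(as.vector(s))
  se <- sd_entry / sqrt(100 * 101 / 2)
  expect_lt(abs(mean(s)), 3 * se)
})

test_that("simulated datasets are balanced, symmetric and reproducible", {
  pair <- generate_base_pair(25, seed = 2)
  spec <- simulation_spec(5, 2, seed = 11)
  ds <- simulate_dataset(pair, spec)
  expect_s3_class(ds, "connectome_dataset")
  d <- dataset_dims(ds)
  expect_identical(unname(d), c(150L, 1L, 25L))
  expect_identical(as.integer(table(ds$labels)), c(75L, 75L))
  expect_length(ds$modified_roi_ids, 5L)
  for (i in c(1L, 80L, 150L)) {
    m <- matrix(ds$data[i, 1, , ], 25, 25)
    expect_lt(max(abs(m - t(m))), 1e-9)
  }
  expect_identical(simulate_dataset(pair, spec)$data, ds$data)
  expect_error(simulation_spec(5, -1), "noise_weight")
})

test_that("zero noise and zero modification collapse to the healthy base", {
  pair <- generate_base_pair(10, seed = 3)
  ds <- simulate_dataset(pair, simulation_spec(0, 0, replicas_per_class = 4,
                                               seed = 1))
  for (i in 1:8) {
    expect_equal(matrix(ds$data[i, 1, , ], 10, 10), pair$healthy)
  }
  expect_null(ds$modified_roi_ids)
})

test_that("class separation shrinks relative to spread as noise grows", {
  pair <- generate_base_pair(50, seed = 6)
  ratio <- vapply(c(1, 4, 8), function(w) {
    ds <- simulate_dataset(pair, simulation_spec(10, w,
                                                 replicas_per_class = 15L,
                                                 seed = 13))
    x <- matrix(ds$data, nrow = 30)    # instances x flattened entries
    c0 <- colMeans(x[ds$labels == 0, ])
    c1 <- colMeans(x[ds$labels == 1, ])
    between <- sqrt(sum((c0 - c1)^2))
    within <- mean(vapply(1:30, function(i) {
      ctr <- if (ds$labels[i] == 0) c0 else c1
      sqrt(sum((x[i, ] - ctr)^2))
    }, numeric(1)))
    between / within
  }, numeric(1))
  expect_true(all(diff(ratio) <= 0))
})
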