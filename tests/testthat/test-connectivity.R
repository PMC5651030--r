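test_that("pearson_matrix matches the correlation formula", {
  x <- c(1, 2, 3); y <- c(1, 3, 2)
  ts <- timeseries_set(cbind(a = x, b = y, c = -x))
  m <- pearson_matrix(ts)
  expect_identical(unname(diag(m)), rep(1, 3))
  expect_equal(m["a", "b"], 0.5)
  expect_equal(m["a", "c"], -1)
  expect_equal(m, t(m))
})

test_that("zero-variance signals are rejected with the ROI named", {
  ts <- timeseries_set(cbind(roiA = c(1, 2, 3), roiB = c(2, 2, 2)))
  expect_error(pearson_matrix(ts), "roiB")
})

test_that("identical series align along the diagonal", {
  x <- sin(seq_len(20))
  r <- dtw_pair(x, x)
  expect_identical(r$distance, 0)
  expect_identical(r$path_length, 20L)
  expect_identical(r$relative_path_length, 0)
})

test_that("a unit shift is absorbed at zero cost with a 5-cell path", {
  r <- dtw_pair(c(0, 0, 1, 0), c(0, 1, 0, 0),
                dtw_params(window_radius = 3, znormalize = FALSE))
  expect_identical(r$distance, 0)
  expect_identical(r$path_length, 5L)
  # exhaustive enumeration agrees
  oracle <- dtw_oracle_enum(c(0, 0, 1, 0), c(0, 1, 0, 0))
  expect_identical(oracle$distance, 0)
  expect_true(5L %in% oracle$optimal_lengths)
})

test_that("full-band DTW equals the brute-force oracle on short series", {
  for (s in 1:10) {
    t_len <- sample(4:12, 1)
    x <- ccnn:::with_seed(s, rnorm(t_len))
    y <- ccnn:::with_seed(s + 100, rnorm(t_len))
    for (cost in c("absolute", "squared")) {
      r <- dtw_pair(x, y, dtw_params(window_radius = t_len - 1,
                                     local_cost = cost, znormalize = FALSE))
      expect_equal(r$distance,
                   dtw_oracle_cost(x, y, squared = cost == "squared"))
    }
  }
})

test_that("banded DTW matches path enumeration restricted to the band", {
  for (s in 1:5) {
    x <- ccnn:::with_seed(s, rnorm(6))
    y <- ccnn:::with_seed(s + 50, rnorm(6))
    for (r in 1:5) {
      got <- dtw_pair(x, y, dtw_params(window_radius = r,
                                       znormalize = FALSE))
      oracle <- dtw_oracle_enum(x, y, radius = r)
      expect_equal(got$distance, oracle$distance)
      expect_true(got$path_length %in% oracle$optimal_lengths)
    }
  }
})

test_that("distance is monotone non-increasing in the band radius", {
  x <- ccnn:::with_seed(21, rnorm(30))
  y <- ccnn:::with_seed(22, rnorm(30))
  d <- vapply(c(1, 3, 6, 12, 29), function(r) {
    dtw_pair(x, y, dtw_params(window_radius = r))$distance
  }, numeric(1))
  expect_true(all(diff(d) <= 1e-12))
})

test_that("warping absorbs small delays that pointwise comparison cannot", {
  t_len <- 40L
  for (s in 1:20) {
    ph <- ccnn:::with_seed(s, runif(3, 0, 2 * pi))
    x <- sin(2 * pi * seq_len(t_len) / t_len + ph[1]) +
      0.5 * sin(4 * pi * seq_len(t_len) / t_len + ph[2])
    y <- x[c(3:t_len, 1:2)]                       # periodic delay of 2 samples
    aligned <- dtw_pair(x, y, dtw_params(window_radius = 4))$distance
    pointwise <- dtw_pair(x, y, dtw_params(window_radius = 0))$distance
    expect_lt(aligned, pointwise)
  }
})

test_that("dtw_pair validates its inputs", {
  expect_error(dtw_pair(1:5, 1:4), "equal length")
  expect_error(dtw_pair(rep(1, 5), 1:5, dtw_params(znormalize = TRUE)),
               "constant")
  expect_error(dtw_pair(1:5, 2:6, dtw_params(window_radius = 5)),
               "window_radius")
})

test_that("dtw_matrices agrees with independent pairwise calls", {
  sig <- ccnn:::with_seed(33, matrix(rnorm(5 * 30), 30, 5))
  ts <- timeseries_set(sig, roi_names = paste0("r", 1:5))
  params <- dtw_params(window_radius = 5)
  mats <- dtw_matrices(ts, params)
  expect_equal(mats$distance, t(mats$distance))
  expect_equal(mats$path_length, t(mats$path_length))
  expect_identical(unname(diag(mats$distance)), rep(0, 5))
  expect_identical(unname(diag(mats$path_length)), rep(0, 5))
  for (a in 1:4) for (b in (a + 1):5) {
    r <- dtw_pair(sig[, a], sig[, b], params)
    expect_equal(unname(mats$distance[a, b]), r$distance)
    expect_equal(unname(mats$path_length[a, b]), r$relative_path_length)
  }
  raw <- dtw_matrices(ts, params, path_length = "raw")
  expect_identical(unname(diag(raw$path_length)), rep(30, 5))
})

test_that("identical signals give an all-zero distance matrix", {
  sig <- cbind(sin(1:25), sin(1:25))
  mats <- dtw_matrices(timeseries_set(sig))
  expect_identical(unname(mats$distance), matrix(0, 2, 2))
})
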