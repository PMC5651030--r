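# Independent oracles and fixture builders used across the suite.

# Memoized recursive DTW cost (full band, no window), written independently
# of the package's dynamic-programming kernel.
dtw_oracle_cost <- function(x, y, squared = FALSE) {
  t <- length(x)
  local_cost <- function(i, j) {
    d <- x[i] - y[j]
    if (squared) d * d else abs(d)
  }
  memo <- matrix(NA_real_, t, t)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(local_cost(1, 1))
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    memo[i, j] <<- local_cost(i, j) + best
    memo[i, j]
  }
  rec(t, t)
}

# Exhaustive enumeration of every monotonic warping path (small T only).
# Returns the minimal cost and the set of path lengths attaining it,
# optionally restricted to a Sakoe-Chiba band.
dtw_oracle_enum <- function(x, y, squared = FALSE, radius = Inf) {
  t <- length(x)
  local_cost <- function(i, j) {
    d <- x[i] - y[j]
    if (squared) d * d else abs(d)
  }
  env <- new.env()
  env$best <- Inf
  env$lengths <- integer(0)
  walk <- function(i, j, acc, len) {
    if (abs(i - j) > radius) return()
    acc <- acc + local_cost(i, j)
    if (i == t && j == t) {
      if (acc < env$best - 1e-12) {
        env$best <- acc
        env$lengths <- len
      } else if (acc <= env$best + 1e-12) {
        env$lengths <- union(env$lengths, len)
      }
      return()
    }
    if (i < t) walk(i + 1, j, acc, len + 1)
    if (j < t) walk(i, j + 1, acc, len + 1)
    if (i < t && j < t) walk(i + 1, j + 1, acc, len + 1)
  }
  walk(1, 1, 0, 1)
  list(distance = env$best, optimal_lengths = sort(env$lengths))
}

# Factorial-form binomial CDF (spec's direct summation, n small).
binom_cdf_oracle <- function(n, k, p) {
  sum(vapply(0:k, function(i) {
    factorial(n) / (factorial(i) * factorial(n - i)) * p^i * (1 - p)^(n - i)
  }, numeric(1)))
}

# Small simulated benchmark dataset.
make_sim_dataset <- function(n_rois, n_modified, noise_weight, seed = 1L,
                             replicas = 75L) {
  pair <- generate_base_pair(n_rois, seed = seed)
  simulate_dataset(pair, simulation_spec(n_modified, noise_weight,
                                         replicas_per_class = replicas,
                                         seed = seed + 1L))
}

# Low-noise, clearly separable two-class toy dataset (capacity checks).
make_toy_dataset <- function(n_rois = 8L, replicas = 10L, seed = 3L) {
  make_sim_dataset(n_rois, n_modified = 3L, noise_weight = 0.05,
                   seed = seed, replicas = replicas)
}

fast_config <- function(kind, dataset, ...) {
  d <- dataset_dims(dataset)
  model_config(kind, n_rois = d[["rois"]], n_channels = d[["channels"]], ...)
}
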