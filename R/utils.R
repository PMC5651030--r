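#' @useDynLib ccnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor pbinom rnorm runif sd
NULL

# Classed condition for argument/schema validation failures so callers
# (and the command-line wrapper) can distinguish bad input from bugs.
stop_invalid <- function(...) {
  msg <- paste0(...)
  stop(structure(
    class = c("ccnn_invalid", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_invalid(...)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x) && x >= min
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Keeps every stochastic operation
# reproducible without clobbering the user's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream index, kept inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(stream) * 7919) %% 2147483647)
}

is_symmetric_tol <- function(m, tol) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}
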