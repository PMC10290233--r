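# Independent oracles the implementation is checked against.

# Exhaustive enumeration over all partitions of the sorted values into k
# contiguous intervals; returns the minimal total within-cluster sum of
# squares. Brute force on purpose: it shares no code with the DP.
oracle_wcss <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  seg_cost <- function(a, b) {
    seg <- x[a:b]
    sum((seg - mean(seg))^2)
  }
  if (k == 1L) return(seg_cost(1L, n))
  stopifnot(k <= n)
  best <- Inf
  splits <- utils::combn(n - 1L, k - 1L)
  for (j in seq_len(ncol(splits))) {
    bounds <- c(0L, splits[, j], n)
    tot <- 0
    for (c in seq_len(k)) tot <- tot + seg_cost(bounds[c] + 1L, bounds[c + 1L])
    if (tot < best) best <- tot
  }
  best
}

# Random sparse non-negative integer count matrix with unique symbols.
random_counts <- function(m = 8L, n = 6L, seed = 1L, max_count = 20L) {
  set.seed(seed)
  vals <- matrix(rpois(m * n, 1.2) * rbinom(m * n, 1, 0.6), m, n)
  vals[rowSums(vals) == 0, 1L] <- 1L
  dimnames(vals) <- list(sprintf("BC%03d", seq_len(m)),
                         sprintf("G%03d", seq_len(n)))
  vals
}

# The synthetic benchmark and its fit, computed once per test session.
.bench_env <- new.env(parent = emptyenv())
benchmark_fixture <- function() {
  if (is.null(.bench_env$fit)) {
    .bench_env$sim <- simulate_joint(seed = 42)
    .bench_env$fit <- speck(.bench_env$sim$counts, seed = 42)
  }
  list(sim = .bench_env$sim, fit = .bench_env$fit)
}
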