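#' Randomized truncated singular value decomposition
#'
#' Computes a truncated SVD of rank `min(max_rank, m - 1, n)` by
#' random range projection with Gaussian test vectors, subspace (power)
#' iterations and QR re-orthonormalization (the Halko-Martinsson-Tropp
#' scheme). The matrix is not centered: downstream rank selection works on
#' the standard deviations of the *non-centered* sample principal
#' components. With a fixed `seed` the output is bit-reproducible on one
#' platform.
#'
#' @param x Cells x genes numeric matrix, dense or sparse (typically the
#'   output of [log_normalize()]).
#' @param max_rank Upper bound on the decomposition rank; default 100.
#' @param seed Integer seed for the Gaussian test matrix.
#' @param power_iter Number of subspace iterations; default 2.
#' @param oversample Extra sampled dimensions beyond the target rank;
#'   default 10. With the defaults, small matrices (sampled dimension
#'   reaching `min(m, n)`) are decomposed to full working precision.
#' @return An object of class `"speck_svd"`: list with orthonormal `u`
#'   (m x r), non-increasing singular values `d` (length r), orthonormal
#'   `v` (n x r), the rank `r`, the dimensions `m`, `n`, dimnames of `x`,
#'   and the seed used.
#' @references Halko, N., Martinsson, P.-G. and Tropp, J.A. (2011) Finding
#'   structure with randomness. SIAM Review 53(2), 217-288.
#' @export
randomized_svd <- function(x, max_rank = 100L, seed = 42L,
                           power_iter = 2L, oversample = 10L) {
  m <- nrow(x); n <- ncol(x)
  if (max_rank < 2L) stop("max_rank must be at least 2")
  if (m < 2L || n < 2L) stop("matrix must be at least 2 x 2")
  r <- min(max_rank, m - 1L, n)
  l <- min(r + oversample, n)

  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  omega <- matrix(stats::rnorm(n * l), n, l)

  y <- as.matrix(x %*% omega)
  if (all(y == 0)) stop("degenerate all-zero matrix")
  q <- qr.Q(qr(y))
  for (i in seq_len(power_iter)) {
    z <- qr.Q(qr(as.matrix(Matrix::crossprod(x, q))))
    q <- qr.Q(qr(as.matrix(x %*% z)))
  }
  b <- as.matrix(Matrix::crossprod(q, x))     # l x n
  sv <- svd(b, nu = r, nv = r)

  u <- q %*% sv$u
  v <- sv$v
  d <- sv$d[seq_len(r)]
  # deterministic sign convention: largest-magnitude entry of each left
  # vector is positive
  for (j in seq_len(r)) {
    s <- sign(u[which.max(abs(u[, j])), j])
    if (s < 0) { u[, j] <- -u[, j]; v[, j] <- -v[, j] }
  }
  structure(list(u = u, d = d, v = v, r = r, m = m, n = n,
                 dimnames = dimnames(x), seed = seed),
            class = "speck_svd")
}

#' @export
print.speck_svd <- function(x, ...) {
  cat("Truncated randomized SVD: rank", x$r, "of a", x$m, "x", x$n,
      "matrix\n")
  cat("Leading singular values:",
      paste(signif(utils::head(x$d, 5L), 4L), collapse = ", "),
      if (x$r > 5L) "..." else "", "\n")
  invisible(x)
}

#' Select the reconstruction rank from a singular spectrum
#'
#' Implements the elbow-style heuristic used by the abundance pipeline: the
#' standard deviations of the non-centered principal components,
#' \eqn{\sigma_i / \sqrt{m - 1}}, are differenced; the absolute consecutive
#' differences are rounded (default 2 decimals, matching the 0.01
#' granularity of the threshold) and run-length encoded; among runs whose
#' value is at least `delta` and whose length is at least `min_run`, the run
#' with the smallest value is taken (the earliest on ties) and the selected
#' rank is the 1-based position of that run's first element plus one.
#'
#' If no run qualifies, the full computed rank is used with a warning; a
#' selection below 2 is clamped to 2 with a warning (a rank-1
#' reconstruction makes per-gene clustering degenerate).
#'
#' @param x A `"speck_svd"` object, or a numeric vector of component
#'   standard deviations (already on the stdev scale).
#' @param m Number of cells; required when `x` is a `"speck_svd"` object it
#'   is taken from the object.
#' @param delta Minimum rounded drop for a run to qualify; default 0.01.
#' @param min_run Minimum run length; default 2.
#' @param digits Decimals the drops are rounded to before run-length
#'   encoding; default 2. Without rounding, floating-point drops are almost
#'   surely distinct and every run has length one.
#' @param roc How the drop between consecutive standard deviations is
#'   measured: `"absolute"` (default) uses `|s_i - s_{i+1}|`; `"relative"`
#'   divides by `s_i`.
#' @return An object of class `"speck_rank"`: list with `k` (selected
#'   rank), `stdevs`, `rate_of_change`, `rounded_roc`, `runs` (data frame
#'   of value/length), and logical `fallback`.
#' @examples
#' s <- c(10, 8, 6, 4, 3.99, 3.98, 3.98, 3.98)
#' select_rank(s)$k  # 5
#' @export
select_rank <- function(x, m = NULL, delta = 0.01, min_run = 2L,
                        digits = 2L, roc = c("absolute", "relative")) {
  roc <- match.arg(roc)
  stdevs <- if (inherits(x, "speck_svd")) {
    x$d / sqrt(x$m - 1)
  } else {
    as.numeric(x)
  }
  r <- length(stdevs)
  if (r < 3L) stop("need at least 3 components to select a rank, got ", r)

  rdiff <- abs(diff(stdevs))
  if (roc == "relative") rdiff <- rdiff / utils::head(stdevs, -1L)
  rounded <- round(rdiff, digits)
  rl <- rle(rounded)
  qual <- which(rl$values >= delta & rl$lengths >= min_run)

  fallback <- length(qual) == 0L
  if (fallback) {
    warning("no run of rounded stdev drops >= ", delta, " with length >= ",
            min_run, "; falling back to full rank k = ", r)
    k <- r
  } else {
    pick <- qual[which.min(rl$values[qual])]   # which.min takes the first tie
    start <- if (pick == 1L) 1L else sum(rl$lengths[seq_len(pick - 1L)]) + 1L
    k <- start + 1L
  }
  if (k < 2L) {
    warning("selected rank below 2; clamped to 2")
    k <- 2L
  }
  structure(list(k = as.integer(k), stdevs = stdevs, rate_of_change = rdiff,
                 rounded_roc = rounded,
                 runs = data.frame(value = rl$values, length = rl$lengths),
                 delta = delta, min_run = as.integer(min_run),
                 digits = as.integer(digits), fallback = fallback),
            class = "speck_rank")
}

#' @export
print.speck_rank <- function(x, ...) {
  cat("Rank selection over", length(x$stdevs), "components: k =", x$k,
      if (x$fallback) "(fallback: no qualifying run)" else "", "\n")
  cat("Runs of rounded stdev drops (value x length):",
      paste(sprintf("%gx%d", x$runs$value, x$runs$length), collapse = ", "),
      "\n")
  invisible(x)
}

#' Reduced-rank reconstruction from truncated factors
#'
#' Multiplies the truncated factors back together,
#' \eqn{\hat X = U_{:,1:k}\, \mathrm{diag}(d_{1:k})\, V_{:,1:k}^T}.
#' By the Eckart-Young theorem this is the best rank-`k` approximation of
#' the decomposed matrix in Frobenius norm, so the reconstruction error is
#' non-increasing in `k`.
#'
#' @param factors A `"speck_svd"` object.
#' @param k Reconstruction rank, between 1 and `factors$r`.
#' @return Dense m x n matrix (may contain negative entries) with the
#'   original dimnames and attribute `rank_used`.
#' @export
reconstruct <- function(factors, k) {
  stopifnot(inherits(factors, "speck_svd"))
  if (k < 1L || k > factors$r)
    stop("k must be in [1, ", factors$r, "], got ", k)
  ix <- seq_len(k)
  out <- factors$u[, ix, drop = FALSE] %*%
    (factors$d[ix] * t(factors$v[, ix, drop = FALSE]))
  dimnames(out) <- factors$dimnames
  attr(out, "rank_used") <- as.integer(k)
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
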