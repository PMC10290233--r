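#' Optimal univariate k-means with a fixed number of clusters
#'
#' Partitions a numeric vector into exactly `k` clusters minimizing the
#' total within-cluster sum of squared deviations from the cluster means.
#' Because optimal 1D clusters are intervals of the sorted values, the
#' global optimum is found by dynamic programming over the sorted distinct
#' values (weighted by multiplicity), filled by divide and conquer in
#' O(k u log u) for u distinct values. The result is deterministic: there is
#' no dependence on initial centers, and equal values are never split across
#' a cluster boundary.
#'
#' @param values Numeric vector to cluster.
#' @param k Number of clusters; must not exceed the number of distinct
#'   values.
#' @return An object of class `"ckmeans1d"`: list with `assignments`
#'   (labels 1..k in original input order, label order = ascending center),
#'   `centers` (strictly increasing cluster means), `sizes`, `wcss` (total
#'   within-cluster sum of squares) and `k`.
#' @examples
#' ckmeans_fixed_k(c(-1, 2, 4, 5, 6), 2)$wcss  # 6.5
#' @references Wang, H. and Song, M. (2011) Ckmeans.1d.dp: optimal k-means
#'   clustering in one dimension by dynamic programming. The R Journal 3(2).
#' @export
ckmeans_fixed_k <- function(values, k) {
  if (length(values) == 0L) stop("empty input")
  if (anyNA(values)) stop("NA values not supported")
  u <- sort(unique(values))
  if (k < 1L) stop("k must be at least 1")
  if (k > length(u))
    stop("k = ", k, " exceeds the number of distinct values (", length(u), ")")
  .ckmeans_build(values, u, as.integer(k), kmax_run = as.integer(k))
}

#' Optimal univariate k-means with model-based choice of k
#'
#' Runs the same dynamic program as [ckmeans_fixed_k()] for every cluster
#' number in `kmin..kmax` and selects among them with a Gaussian-mixture
#' Bayesian information criterion: each cluster is modeled as a Gaussian
#' with its own mean, variance and mixing weight `size/n`; `BIC(k) =
#' 2 loglik - (3k - 1) ln n` and the `k` maximizing it wins (smallest on
#' ties). Zero-variance clusters use a floor variance of
#' `(range(values) * 1e-6)^2`; to keep that floor from letting singleton
#' clusters inflate the likelihood without bound, partitions containing a
#' one-point cluster are excluded from the comparison (a lone outlier is
#' not a sub-population). Consequences relied on downstream: constant
#' input yields `k = 1`, and well-separated tight groups are recovered
#' exactly (a unimodal cloud is *not* split, because the classification
#' likelihood of splitting a single Gaussian loses more in mixing weight
#' than it gains in spread).
#'
#' @param values Numeric vector to cluster.
#' @param kmin,kmax Range of cluster numbers to examine; defaults 1 and 4.
#'   `kmax` above the number of distinct values is clamped down (with a
#'   warning unless `quiet`).
#' @param quiet Suppress the clamping warning (used by the per-gene
#'   thresholding loop, which reports clamp counts in aggregate).
#' @return A `"ckmeans1d"` object as in [ckmeans_fixed_k()], with an extra
#'   element `bic` (one value per examined k).
#' @export
select_k <- function(values, kmin = 1L, kmax = 4L, quiet = FALSE) {
  if (length(values) == 0L) stop("empty input")
  if (anyNA(values)) stop("NA values not supported")
  stopifnot(kmin >= 1L, kmin <= kmax)
  u <- sort(unique(values))
  nu <- length(u)
  if (kmax > nu) {
    if (!quiet)
      warning("kmax = ", kmax, " exceeds the number of distinct values (",
              nu, "); clamped")
    kmax <- nu
    if (kmin > kmax) kmin <- kmax
  }
  if (nu == 1L) {
    res <- .ckmeans_build(values, u, 1L, kmax_run = 1L)
    res$bic <- NA_real_
    return(res)
  }

  w <- tabulate(match(values, u), nbins = nu)
  dp <- .ckmeans_dp(u, as.numeric(w), as.integer(kmax))
  n <- length(values)
  vfloor <- ((u[nu] - u[1L]) * 1e-6)^2
  bic <- rep(NA_real_, kmax)
  for (k in seq.int(kmin, kmax)) {
    st <- dp$starts[[k]]
    ll <- 0
    for (c in seq_len(k)) {
      i0 <- st[c]
      i1 <- if (c < k) st[c + 1L] - 1L else nu
      idx <- seq.int(i0, i1)
      nc <- sum(w[idx])
      if (k > 1L && nc == 1L) { ll <- NA_real_; break }
      mu <- sum(w[idx] * u[idx]) / nc
      ss <- sum(w[idx] * (u[idx] - mu)^2)
      v <- max(ss / nc, vfloor)
      ll <- ll + nc * log(nc / n) - nc / 2 * log(2 * pi * v) - ss / (2 * v)
    }
    bic[k] <- if (is.na(ll)) NA_real_ else 2 * ll - (3 * k - 1) * log(n)
  }
  if (all(is.na(bic))) {
    kbest <- kmin
  } else {
    kbest <- which.max(replace(bic, is.na(bic), -Inf))  # first max = smallest k
  }
  res <- .ckmeans_build(values, u, as.integer(kbest), dp = dp,
                        kmax_run = as.integer(kmax))
  res$bic <- bic
  res
}

#' @export
print.ckmeans1d <- function(x, ...) {
  cat("Optimal 1D k-means: k =", x$k, "clusters over", sum(x$sizes),
      "values\n")
  cat("Centers:", paste(signif(x$centers, 4L), collapse = ", "), "\n")
  cat("Sizes:  ", paste(x$sizes, collapse = ", "), "\n")
  cat("WCSS:   ", format(x$wcss), "\n")
  invisible(x)
}

# Shared assembly: run (or reuse) the DP and map distinct-value clusters
# back to the original input order.
.ckmeans_build <- function(values, u, k, dp = NULL, kmax_run = k) {
  nu <- length(u)
  w <- tabulate(match(values, u), nbins = nu)
  if (is.null(dp)) dp <- .ckmeans_dp(u, as.numeric(w), kmax_run)
  st <- dp$starts[[k]]
  lab_distinct <- rep(seq_len(k), times = diff(c(st, nu + 1L)))
  assignments <- lab_distinct[match(values, u)]
  centers <- vapply(seq_len(k), function(c)
    mean(values[assignments == c]), numeric(1))
  sizes <- tabulate(assignments, nbins = k)
  structure(list(assignments = assignments, centers = centers,
                 sizes = sizes, wcss = dp$wcss[k], k = as.integer(k)),
            class = "ckmeans1d")
}
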