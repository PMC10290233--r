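#' Clustered thresholding of one reconstructed gene
#'
#' Clusters the reconstructed expression values of a single gene with
#' [select_k()]. If more than one cluster is found, every cell belonging to
#' the cluster with the lowest mean is set to exactly zero and all values in
#' higher clusters are preserved verbatim (including negatives); if only one
#' cluster is found, the column is returned unchanged. This exploits the
#' bimodality of surface-protein expression: the lowest cluster is read as
#' the "off" sub-population.
#'
#' @param column Numeric vector: one gene's reconstructed values across
#'   cells (may contain negatives and exact zeros).
#' @param kmin,kmax Cluster-number range passed to [select_k()];
#'   defaults 1 and 4.
#' @return List with `values` (thresholded column), `clusters_found`,
#'   `thresholded` (logical, `clusters_found > 1`) and `zeroed_count`
#'   (cells assigned to the lowest cluster, counted whether or not they
#'   were already zero).
#' @examples
#' threshold_gene(c(0, 0.1, 0.12, 3.0, 3.1))$values  # 0 0 0 3.0 3.1
#' @export
threshold_gene <- function(column, kmin = 1L, kmax = 4L) {
  cl <- select_k(column, kmin = kmin, kmax = kmax, quiet = TRUE)
  if (cl$k > 1L) {
    low <- cl$assignments == 1L       # label 1 = lowest center
    column[low] <- 0
    list(values = column, clusters_found = cl$k, thresholded = TRUE,
         zeroed_count = sum(low))
  } else {
    list(values = column, clusters_found = 1L, thresholded = FALSE,
         zeroed_count = 0L)
  }
}

#' Estimate relative surface-receptor abundance from scRNA-seq counts
#'
#' Fits the full unsupervised abundance estimator to a cells x genes count
#' matrix: (1) per-cell log-normalization ([log_normalize()]); (2) rank-100
#' randomized SVD of the normalized matrix ([randomized_svd()]); (3) rank
#' selection by the run-length heuristic on the drops between successive
#' principal-component standard deviations ([select_rank()]); (4) reduced-
#' rank reconstruction ([reconstruct()]); (5) per-gene clustered
#' thresholding ([threshold_gene()]): genes whose reconstructed values form
#' more than one cluster have their lowest-mean cluster zeroed; genes
#' forming a single cluster pass through untouched. The result estimates
#' *relative* abundance: values are comparable across cells within a gene,
#' not across genes.
#'
#' @param counts Cells x genes non-negative integer count matrix (dense or
#'   sparse) with cell barcodes as rownames and gene symbols as colnames.
#' @param max_rank Rank of the initial truncated SVD; default 100.
#' @param kmin,kmax Cluster-number range for per-gene thresholding;
#'   defaults 1 and 4 (performance is insensitive to `kmax` over roughly
#'   3-15 for well-separated bimodal genes).
#' @param scale_factor Library-size scale factor; default 10000.
#' @param seed Seed for the randomized SVD; the whole fit is deterministic
#'   given `counts` and `seed`.
#' @param delta,min_run,digits Rank-selection tuning, see [select_rank()].
#' @param clamp_negatives If `TRUE`, surviving negative reconstructed
#'   values are clamped to zero after thresholding; default `FALSE`
#'   (higher-cluster values are preserved as reconstructed).
#' @return An object of class `"speck"`: list with `abundance` (dense
#'   m x n estimate matrix), `rank_used`, `rank_selection` (a
#'   `"speck_rank"` object), `per_gene` (data frame: gene,
#'   clusters_found, thresholded, zeroed_count), `kmax_clamped` (number of
#'   genes whose distinct-value count forced a smaller `kmax`), dimensions,
#'   `seed` and the matched call. Supports `print`, `summary`, `fitted`
#'   and `plot`.
#' @examples
#' sim <- simulate_joint(n_cells = 200, n_genes = 60, n_receptors = 4,
#'                       seed = 7)
#' fit <- speck(sim$counts, max_rank = 30, seed = 7)
#' fit
#' head(fit$per_gene)
#' @export
speck <- function(counts, max_rank = 100L, kmin = 1L, kmax = 4L,
                  scale_factor = 1e4, seed = 42L, delta = 0.01,
                  min_run = 2L, digits = 2L, clamp_negatives = FALSE) {
  cl <- match.call()
  counts <- validate_counts(counts)
  norm <- log_normalize(counts, scale_factor = scale_factor)
  fac <- randomized_svd(norm, max_rank = max_rank, seed = seed)
  rsel <- select_rank(fac, delta = delta, min_run = min_run, digits = digits)
  rec <- reconstruct(fac, rsel$k)

  n <- ncol(rec)
  per_gene <- data.frame(gene = colnames(rec) %||% paste0("g", seq_len(n)),
                         clusters_found = integer(n),
                         thresholded = logical(n),
                         zeroed_count = integer(n))
  clamped <- 0L
  abundance <- rec
  for (j in seq_len(n)) {
    colj <- rec[, j]
    if (length(unique(colj)) < kmax) clamped <- clamped + 1L
    th <- threshold_gene(colj, kmin = kmin, kmax = kmax)
    abundance[, j] <- th$values
    per_gene$clusters_found[j] <- th$clusters_found
    per_gene$thresholded[j] <- th$thresholded
    per_gene$zeroed_count[j] <- th$zeroed_count
  }
  if (clamp_negatives) abundance[abundance < 0] <- 0
  attr(abundance, "rank_used") <- NULL

  structure(list(abundance = abundance, rank_used = rsel$k,
                 rank_selection = rsel, per_gene = per_gene,
                 kmax_clamped = clamped, m = nrow(abundance),
                 n = ncol(abundance), seed = seed,
                 scale_factor = scale_factor,
                 clamp_negatives = clamp_negatives, call = cl),
            class = "speck")
}

#' @export
print.speck <- function(x, ...) {
  cat("Surface-receptor abundance estimate (reduced-rank reconstruction +",
      "clustered thresholding)\n")
  cat("  ", x$m, "cells x", x$n, "genes; reconstruction rank", x$rank_used,
      if (x$rank_selection$fallback) "(fallback)" else "", "\n")
  cat("  ", sum(x$per_gene$thresholded), "of", x$n,
      "genes thresholded (>1 cluster found)\n")
  invisible(x)
}

#' @describeIn speck Extract the fitted abundance matrix.
#' @param object,x A fitted `"speck"` object.
#' @param ... Unused.
#' @export
fitted.speck <- function(object, ...) object$abundance

#' @export
summary.speck <- function(object, ...) {
  pg <- object$per_gene
  structure(list(m = object$m, n = object$n, rank_used = object$rank_used,
                 fallback = object$rank_selection$fallback,
                 cluster_table = table(pg$clusters_found),
                 n_thresholded = sum(pg$thresholded),
                 zeroed_summary = summary(pg$zeroed_count[pg$thresholded]),
                 frac_zero = mean(object$abundance == 0),
                 seed = object$seed),
            class = "summary.speck")
}

#' @export
print.summary.speck <- function(x, ...) {
  cat("Receptor abundance estimation summary\n")
  cat("  Matrix: ", x$m, " cells x ", x$n, " genes\n", sep = "")
  cat("  Reconstruction rank: ", x$rank_used,
      if (x$fallback) " (fallback: no qualifying stdev-drop run)" else "",
      "\n", sep = "")
  cat("  Clusters found per gene:\n")
  print(x$cluster_table)
  cat("  Genes thresholded: ", x$n_thresholded, "\n", sep = "")
  if (x$n_thresholded > 0) {
    cat("  Cells zeroed per thresholded gene:\n")
    print(x$zeroed_summary)
  }
  cat("  Zero fraction of estimate matrix: ",
      sprintf("%.3f", x$frac_zero), "\n", sep = "")
  invisible(x)
}

#' @describeIn speck Scree-style diagnostic plot: component standard
#'   deviations with the selected rank marked, and the rounded drops used
#'   by the run-length rule.
#' @export
plot.speck <- function(x, ...) {
  rs <- x$rank_selection
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(rs$stdevs, type = "b", pch = 16, cex = 0.6,
       xlab = "component", ylab = "stdev (non-centered PC)",
       main = "Singular spectrum", ...)
  graphics::abline(v = rs$k, lty = 2)
  graphics::mtext(paste("k =", rs$k), side = 3, line = -1.5, adj = 0.9,
                  cex = 0.8)
  plot(rs$rounded_roc, type = "h",
       xlab = "component pair", ylab = "rounded |stdev drop|",
       main = "Rate of change", ...)
  graphics::abline(h = rs$delta, lty = 3)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
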