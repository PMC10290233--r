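#' Log-normalize a count matrix
#'
#' Per-cell library-size normalization followed by a log transform, the
#' standard Seurat-style scheme: each count is divided by the total count of
#' its cell, multiplied by `scale_factor`, incremented by a pseudocount of
#' one and natural-log transformed,
#' \deqn{y_{ij} = \ln(1 + c_{ij} \cdot s / \sum_j c_{ij}).}
#' Zeros map to zeros, so the sparsity pattern is preserved and sparse input
#' is normalized without densification.
#'
#' @param counts Cells x genes count matrix (dense or sparse), e.g. from
#'   [read_mtx()] or [simulate_joint()].
#' @param scale_factor Positive scale factor \eqn{s}; default 10000.
#' @return A matrix of the same class and dimnames, natural-log scale, with
#'   attribute `scale_factor`.
#' @examples
#' m <- matrix(c(1, 0, 3, 2, 2, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
#' log_normalize(m)[1, 1]  # ln(1 + 1 * 10000 / 4) = ln(2501)
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  stopifnot(is.numeric(scale_factor), length(scale_factor) == 1L,
            scale_factor > 0)
  rs <- Matrix::rowSums(counts)
  if (any(rs == 0)) {
    bad <- rownames(counts)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("cell(s) with zero total count: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (methods::is(counts, "sparseMatrix")) {
    out <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
    out@x <- log1p(out@x * scale_factor / rs[out@i + 1L])
  } else {
    out <- log1p(counts * (scale_factor / rs))
  }
  attr(out, "scale_factor") <- scale_factor
  out
}
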