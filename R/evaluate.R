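#' Centered log-ratio normalization of ADT counts
#'
#' Normalizes a cells x antibodies matrix of antibody-derived tag (ADT)
#' counts with the pseudocount form of the centered log-ratio transform used
#' for CITE-seq protein data:
#' \deqn{y = \ln(1 + x / g), \qquad g = \exp(\mathrm{mean}(\ln(1 + x)))}
#' with the geometric mean `g` taken over the chosen margin — per cell
#' across antibodies (default) or per antibody across cells.
#'
#' @param adt Cells x antibodies matrix of raw non-negative counts.
#' @param margin `"cell"` (default) or `"feature"`: the unit over which the
#'   geometric mean is taken.
#' @return Dense numeric matrix of the same shape with attribute
#'   `clr_normalized = TRUE`.
#' @examples
#' m <- rbind(c(1, 4), c(2, 2))
#' clr_normalize(m)[1, ]  # log1p(c(1, 4) / sqrt(10))
#' @export
clr_normalize <- function(adt, margin = c("cell", "feature")) {
  margin <- match.arg(margin)
  if (isTRUE(attr(adt, "clr_normalized")))
    stop("input is already CLR-normalized")
  x <- as.matrix(adt)
  if (any(x < 0)) stop("ADT counts must be non-negative")
  lx <- log1p(x)
  if (margin == "cell") {
    zero <- rowSums(x) == 0
    if (any(zero))
      stop("all-zero cell(s): geometric mean undefined (",
           paste(utils::head(rownames(x)[zero] %||% which(zero), 5L),
                 collapse = ", "), ")")
    g <- exp(rowMeans(lx))
    out <- log1p(x / g)
  } else {
    zero <- colSums(x) == 0
    if (any(zero))
      stop("all-zero antibody column(s): geometric mean undefined")
    g <- exp(colMeans(lx))
    out <- log1p(sweep(x, 2L, g, "/"))
  }
  attr(out, "clr_normalized") <- TRUE
  out
}

#' Build an antibody-to-gene feature map
#'
#' Pairs antibody names with the gene symbols their targets are transcribed
#' from. Antibodies mapping to more than one distinct symbol are excluded
#' (with a message): an ambiguous mapping cannot be scored against a single
#' transcript.
#'
#' @param antibody Character vector of antibody names.
#' @param symbol Character vector of gene symbols, same length.
#' @return Data frame with columns `antibody` and `symbol`, one row per
#'   retained antibody.
#' @export
feature_map <- function(antibody, symbol) {
  stopifnot(length(antibody) == length(symbol))
  df <- unique(data.frame(antibody = as.character(antibody),
                          symbol = as.character(symbol),
                          stringsAsFactors = FALSE))
  nsym <- tapply(df$symbol, df$antibody, function(s) length(unique(s)))
  multi <- names(nsym)[nsym > 1L]
  if (length(multi)) {
    message("excluding ", length(multi),
            " antibody(ies) mapping to multiple gene symbols: ",
            paste(utils::head(multi, 5L), collapse = ", "))
    df <- df[!df$antibody %in% multi, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Per-receptor correlation between abundance estimates and ADT data
#'
#' For every antibody in the feature map whose gene symbol is present in the
#' estimate matrix, computes the correlation between the estimated abundance
#' column and the (CLR-normalized) ADT column over the cells shared by both
#' matrices. Spearman is the default: relative abundance estimates are only
#' meaningful through their ranks. Receptors whose estimate or ADT column is
#' constant have an undefined correlation and are recorded as `NA`, never
#' as zero.
#'
#' @param estimates A fitted [speck] object, or a cells x genes matrix.
#' @param adt Cells x antibodies matrix (CLR-normalized with
#'   [clr_normalize()], or any per-cell protein readout).
#' @param map Data frame with columns `antibody` and `symbol`, e.g. from
#'   [feature_map()].
#' @param method `"spearman"` (default), `"pearson"` or `"kendall"`
#'   (tau-b, tie-adjusted).
#' @return Data frame with one row per evaluated receptor: `receptor`
#'   (gene symbol), `antibody`, `correlation`, `method`.
#' @export
receptor_correlations <- function(estimates, adt, map,
                                  method = c("spearman", "pearson",
                                             "kendall")) {
  method <- match.arg(method)
  if (inherits(estimates, "speck")) estimates <- fitted(estimates)
  if (!all(c("antibody", "symbol") %in% names(map)))
    stop("map must have columns 'antibody' and 'symbol'")
  if (nrow(map) == 0L) stop("empty feature map")
  cells <- intersect(rownames(estimates), rownames(adt))
  if (length(cells) == 0L) stop("no overlapping cell barcodes")
  keep <- map$symbol %in% colnames(estimates) &
    map$antibody %in% colnames(adt)
  map <- map[keep, , drop = FALSE]
  if (nrow(map) == 0L) stop("no antibody resolves to a gene in the estimates")

  corr <- vapply(seq_len(nrow(map)), function(i) {
    e <- as.numeric(estimates[cells, map$symbol[i]])
    a <- as.numeric(adt[cells, map$antibody[i]])
    if (stats::sd(e) == 0 || stats::sd(a) == 0) return(NA_real_)
    stats::cor(e, a, method = method)
  }, numeric(1))
  data.frame(receptor = map$symbol, antibody = map$antibody,
             correlation = corr, method = method,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Proportion of receptors on which each method is best
#'
#' Summarizes competing abundance estimators by the fraction of receptors on
#' which each achieves the highest correlation with the ADT data. Exact ties
#' on a receptor are split fractionally across the tied methods, so the
#' proportions always sum to one. Receptors missing (NA) for any method are
#' dropped (with a message).
#'
#' @param reports Named list (one element per method) of data frames as
#'   returned by [receptor_correlations()], or of named numeric vectors of
#'   per-receptor correlations.
#' @return Named numeric vector of proportions, one per method, summing
#'   to 1.
#' @examples
#' proportion_best(list(
#'   a = c(CD4 = 0.9, CD8 = 0.5, CD14 = 0.7, CD19 = 0.2),
#'   b = c(CD4 = 0.3, CD8 = 0.4, CD14 = 0.6, CD19 = 0.8)))
#' @export
proportion_best <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 methods to compare")
  if (is.null(names(reports)) || any(names(reports) == ""))
    stop("reports must be a named list")
  as_vec <- function(r) {
    if (is.data.frame(r)) stats::setNames(r$correlation, r$receptor) else r
  }
  vecs <- lapply(reports, as_vec)
  common <- Reduce(intersect, lapply(vecs, names))
  if (length(common) == 0L) stop("no receptor shared by all methods")
  mat <- vapply(vecs, function(v) v[common], numeric(length(common)))
  if (length(common) == 1L) mat <- matrix(mat, nrow = 1L,
                                          dimnames = list(common,
                                                          names(reports)))
  ok <- stats::complete.cases(mat)
  if (any(!ok))
    message("dropping ", sum(!ok),
            " receptor(s) with missing correlations")
  mat <- mat[ok, , drop = FALSE]
  if (nrow(mat) == 0L) stop("no receptor with complete correlations")

  wins <- stats::setNames(numeric(ncol(mat)), colnames(mat))
  for (i in seq_len(nrow(mat))) {
    best <- mat[i, ] == max(mat[i, ])
    wins[best] <- wins[best] + 1 / sum(best)
  }
  wins / nrow(mat)
}
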