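#' Simulate paired scRNA-seq counts and ADT readouts with known truth
#'
#' Generates a joint synthetic dataset emulating the structure the abundance
#' estimator targets: sparse non-negative integer RNA counts with low
#' intrinsic rank (a planted-rank log-mean built from cell-type-anchored
#' latent factors), per-gene bimodal on/off expression for a set of receptor
#' genes (each receptor is "on" in a subset of cell types and essentially
#' silent elsewhere), and a paired noisy ADT readout that is monotone in the
#' true per-cell surface-protein level with multiplicative lognormal noise
#' and a Poisson background. Extra zeros are injected into the receptor
#' columns to reach the requested dropout rate. All randomness flows through
#' one seeded generator, so a fixed seed reproduces the dataset
#' bit-for-bit.
#'
#' @param n_cells,n_genes Dataset dimensions; defaults 2000 x 300.
#' @param n_receptors Number of planted receptor genes (the last
#'   `n_receptors` gene columns); default 10.
#' @param n_cell_types Number of discrete cell types; default 4.
#' @param planted_rank Rank of the latent log-mean structure; default 8.
#' @param dropout Probability that a receptor-gene count is zeroed after
#'   sampling, in [0, 1); default 0.2.
#' @param adt_noise Standard deviation of the multiplicative lognormal ADT
#'   noise on the log scale; default 0.3.
#' @param rna_capture Mean receptor transcript count per unit of true
#'   protein level. The default 1 puts receptor genes in the low-count
#'   regime where dropout and shot noise dominate the raw transcript — the
#'   setting reduced-rank denoising exists for; raise it (e.g. 10) to
#'   emulate deeply captured receptors whose raw counts already track the
#'   protein ranks closely.
#' @param seed Integer seed.
#' @param dispersion If `NULL` (default) counts are Poisson; otherwise
#'   negative binomial with this dispersion (`size = 1/dispersion`).
#' @return List of class `"speck_sim"`: `counts` (sparse dgCMatrix, cells x
#'   genes, barcodes/symbols in dimnames), `adt` (cells x antibodies count
#'   matrix, antibody names `"anti-<symbol>"`), `map` (antibody-to-symbol
#'   data frame), and `truth` (cell_types, protein_level matrix with exact
#'   zeros in "off" cells, on_types per receptor, receptor_genes, the
#'   `log_mean` matrix the counts were drawn around, planted_rank, seed).
#' @examples
#' sim <- simulate_joint(n_cells = 100, n_genes = 40, n_receptors = 3,
#'                       seed = 1)
#' dim(sim$counts); colnames(sim$adt)
#' @export
simulate_joint <- function(n_cells = 2000L, n_genes = 300L,
                           n_receptors = 10L, n_cell_types = 4L,
                           planted_rank = 8L, dropout = 0.2,
                           adt_noise = 0.3, rna_capture = 1,
                           seed = 42L, dispersion = NULL) {
  stopifnot(n_receptors <= n_genes,
            planted_rank <= min(n_cells, n_genes),
            dropout >= 0, dropout < 1, adt_noise > 0, rna_capture > 0,
            n_cell_types >= 1L, n_cell_types <= n_cells)
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)

  m <- as.integer(n_cells); n <- as.integer(n_genes)
  p <- as.integer(n_receptors); tt <- as.integer(n_cell_types)
  r <- as.integer(planted_rank)

  cell_types <- sample.int(tt, m, replace = TRUE)
  # latent scores: type anchors plus small within-type jitter -> the
  # log-mean matrix has (numerical) rank planted_rank
  anchors <- matrix(stats::rnorm(tt * r), tt, r)
  scores <- anchors[cell_types, , drop = FALSE] +
    matrix(stats::rnorm(m * r, sd = 0.15), m, r)
  loadings <- matrix(stats::rnorm(r * n, sd = 0.35), r, n)
  lambda <- exp(scores %*% loadings) * 0.8     # typical gene mean ~ 1

  gene_symbols <- sprintf("GENE%04d", seq_len(n))
  rc_idx <- seq.int(n - p + 1L, n)
  gene_symbols[rc_idx] <- sprintf("RCPT%02d", seq_len(p))

  # receptors: on in a proper subset of cell types (at least about half, so
  # rank correlations are not dominated by the tied-at-zero block), with a
  # per-cell lognormal protein level in "on" cells and exact zero in "off"
  szmin <- max(1L, as.integer(ceiling(tt / 2)))
  szmax <- max(tt - 1L, szmin)
  sizes <- seq.int(szmin, szmax)
  on_types <- lapply(seq_len(p), function(i) {
    sort(sample.int(tt, sizes[sample.int(length(sizes), 1L)]))
  })
  protein <- matrix(0, m, p)
  for (i in seq_len(p)) {
    on <- cell_types %in% on_types[[i]]
    base <- stats::runif(1L, 2, 5)
    protein[on, i] <- exp(stats::rnorm(sum(on), mean = log(base), sd = 0.35))
    lambda[, rc_idx[i]] <- 0.02
    lambda[on, rc_idx[i]] <- rna_capture * protein[on, i]  # monotone in protein
  }

  counts <- if (is.null(dispersion)) {
    stats::rpois(m * n, as.vector(lambda))
  } else {
    stats::rnbinom(m * n, size = 1 / dispersion, mu = as.vector(lambda))
  }
  counts <- matrix(counts, m, n)

  if (dropout > 0) {
    drop <- matrix(stats::runif(m * p) < dropout, m, p)
    counts[, rc_idx][drop] <- 0L
  }
  # guard: a cell with zero total count cannot be library-normalized
  empty <- rowSums(counts) == 0L
  if (any(empty)) counts[empty, 1L] <- 1L

  barcodes <- sprintf("CELL%05d", seq_len(m))
  dimnames(counts) <- list(barcodes, gene_symbols)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")

  dimnames(lambda) <- dimnames(counts)
  noise <- matrix(exp(stats::rnorm(m * p, sd = adt_noise)), m, p)
  adt <- matrix(stats::rpois(m * p, 5), m, p) + round(25 * protein * noise)
  antibodies <- paste0("anti-", gene_symbols[rc_idx])
  dimnames(adt) <- list(barcodes, antibodies)
  dimnames(protein) <- list(barcodes, gene_symbols[rc_idx])

  structure(list(
    counts = counts, adt = adt,
    map = feature_map(antibodies, gene_symbols[rc_idx]),
    truth = list(cell_types = cell_types, protein_level = protein,
                 on_types = on_types, receptor_genes = gene_symbols[rc_idx],
                 log_mean = log(lambda), planted_rank = r, seed = seed)),
    class = "speck_sim")
}

#' @export
print.speck_sim <- function(x, ...) {
  cat("Synthetic joint scRNA-seq/ADT dataset:",
      nrow(x$counts), "cells x", ncol(x$counts), "genes,",
      ncol(x$adt), "receptors; planted rank", x$truth$planted_rank,
      "; seed", x$truth$seed, "\n")
  invisible(x)
}

#' Simulate a component standard-deviation sequence with a planted elbow
#'
#' Builds a monotone-decreasing stdev sequence on which the run-length
#' rank-selection rule of [select_rank()] must return `planted_rank`: the
#' drops between successive components are large and mutually distinct up to
#' component `planted_rank - 1`, a matched pair of 0.01 drops sits at the
#' elbow (component pairs `planted_rank - 1` and `planted_rank`), and all
#' later drops decay below 0.005 (rounding to zero). The matched minimal
#' pair is the smallest qualifying run, and its first element's index plus
#' one is exactly `planted_rank`. If `signal_gap < 0.01` every drop is
#' placed below 0.005, so no run qualifies and the rule falls back to the
#' full rank.
#'
#' @param planted_rank Target rank the rule should select; at least 2 and
#'   less than `n_components - 1`.
#' @param n_components Length of the stdev sequence; default 30.
#' @param signal_gap Size scale of the pre-elbow drops; default 0.5.
#' @param seed Integer seed (jitters the large drops without perturbing the
#'   rounded values that drive the rule).
#' @return Numeric vector of length `n_components`, strictly decreasing.
#' @examples
#' select_rank(simulate_spectrum(5, seed = 1))$k  # 5
#' @export
simulate_spectrum <- function(planted_rank, n_components = 30L,
                              signal_gap = 0.5, seed = 42L) {
  p <- as.integer(planted_rank); r <- as.integer(n_components)
  stopifnot(p >= 2L, r >= p + 2L, signal_gap > 0)
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)

  drops <- numeric(r - 1L)
  noise_tail <- 0.002 * 0.9^seq_len(r - 1L) *
    stats::runif(r - 1L, 0.5, 1)                 # < 0.005, rounds to 0
  if (signal_gap < 0.01) {
    drops <- noise_tail
  } else {
    gap <- max(signal_gap, 0.02)
    if (p > 2L) {
      i <- seq_len(p - 2L)
      # strictly separated so rounding to 2 decimals keeps them distinct:
      # each pre-elbow drop sits in its own run of length one
      drops[i] <- gap * (1 + rev(i) / 2) + stats::runif(p - 2L, 0, 0.002)
    }
    drops[c(p - 1L, p)] <- 0.01                  # the minimal matched pair
    if (p + 1L <= r - 1L) {
      j <- seq.int(p + 1L, r - 1L)
      drops[j] <- noise_tail[j]
    }
  }
  top <- 1 + sum(drops) + stats::runif(1L, 0, 0.5)
  top - cumsum(c(0, drops))
}
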