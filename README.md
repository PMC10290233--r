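# speckr

Unsupervised estimation of **relative cell-surface receptor abundance** from
single-cell RNA-seq count matrices.

Many single-cell analyses — cell typing, phenotyping, cell–cell signaling —
hinge on surface-protein levels, but direct protein measurements (CITE-seq
antibody-derived tags, ADT) are scarce and limited to receptors with
available antibodies. The receptor's own transcript is a poor proxy: at
typical capture rates receptor mRNAs are counted in single digits and
riddled with dropout zeros. `speckr` is for analysts who have only an
scRNA-seq count matrix and need per-cell receptor abundance estimates whose
*ranks* track the underlying protein.

## Method

Given an `m x n` matrix of raw counts `C` (cells x genes), the estimator:

1. **Log-normalizes** per cell: `X_ij = ln(1 + C_ij * s / Σ_j C_ij)` with
   scale factor `s = 10 000`.
2. **Decomposes** `X` by a rank-100 randomized SVD (no centering).
3. **Selects the reconstruction rank** `k` from the standard deviations of
   the non-centered principal components, `σ_i / sqrt(m - 1)`: the absolute
   drops between consecutive standard deviations are rounded to two
   decimals and run-length encoded; among runs with value ≥ 0.01 and length
   ≥ 2, the smallest-valued run is taken and `k` is the position of its
   first element plus one — a run-length formalization of the scree-elbow
   rule.
4. **Reconstructs** `X̂ = U_k Σ_k V_kᵀ`, the best rank-`k` approximation.
5. **Thresholds each gene** with optimal univariate k-means (dynamic
   programming over the sorted values, exact, initialization-free): if the
   gene's reconstructed values form more than one cluster (k chosen in 1–4
   by a Gaussian-mixture BIC), every cell in the lowest-mean cluster is set
   to exactly 0 and all other values are preserved. Surface-protein
   expression is typically bimodal — an "off" sub-population plus one or
   more "on" modes — and this per-gene adaptive thresholding is what
   distinguishes the estimator from fixed-quantile thresholding schemes.

The output is a cells x genes matrix of relative abundance estimates plus
per-gene provenance (clusters found, cells zeroed).

## Worked example

Everything is testable without downloads via the built-in generator of
paired scRNA-seq/ADT data with known ground truth:

```r
library(speckr)

sim <- simulate_joint(n_cells = 1000, n_genes = 200, n_receptors = 6, seed = 1)
fit <- speck(sim$counts, seed = 1)
fit
#> Surface-receptor abundance estimate (reduced-rank reconstruction + clustered thresholding)
#>    1000 cells x 200 genes; reconstruction rank 22
#>    72 of 200 genes thresholded (>1 cluster found)
```

The fitted rank (22) is chosen by the scree-elbow rule; 72 of 200 genes
showed a multi-cluster (bimodal or multimodal) reconstruction and had their
lowest cluster zeroed — thresholding is *adaptive*, not universal. Scoring
the estimates against the CLR-normalized ADT ground truth:

```r
adt  <- clr_normalize(sim$adt)
cors <- receptor_correlations(fit, adt, sim$map)
cors
#>   receptor    antibody correlation   method
#> 1   RCPT01 anti-RCPT01   0.7939738 spearman
#> 2   RCPT02 anti-RCPT02   0.5683538 spearman
#> 3   RCPT03 anti-RCPT03   0.5748642 spearman
#> 4   RCPT04 anti-RCPT04   0.8255755 spearman
#> 5   RCPT05 anti-RCPT05   0.8242265 spearman
#> 6   RCPT06 anti-RCPT06   0.6396853 spearman

rna <- receptor_correlations(log_normalize(sim$counts), adt, sim$map)
proportion_best(list(speck = cors, transcript = rna))
#>      speck transcript
#>          1          0
```

Per-receptor Spearman correlations of 0.57–0.83 against the protein ground
truth, and the estimator beats the raw log-normalized transcript on all six
receptors (`proportion_best` = 1): reduced-rank reconstruction recovers the
dropout zeros that cripple the raw transcript.

A shell wrapper with `run` / `simulate` / `evaluate` subcommands is
installed at `system.file("cli/speck-cli.R", package = "speckr")`.

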