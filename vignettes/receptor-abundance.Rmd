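---
title: "Estimating surface-receptor abundance from scRNA-seq by reduced-rank reconstruction and clustered thresholding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating surface-receptor abundance from scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckr)
```

## The problem

Cell-surface receptors drive most of what we want to read off a single-cell
experiment — lineage, activation state, signaling capacity — yet scRNA-seq
measures them only through their transcripts. Receptor mRNAs are typically
captured at a handful of counts per cell, so the raw transcript column is a
mixture of true "off" cells, true "on" cells, and on-cells lost to dropout.
The estimator in this package produces *relative* abundance estimates: values
whose ranks across cells track the underlying protein, suitable for scoring
against CITE-seq antibody-derived tag (ADT) data with rank correlations.
Absolute protein concentrations are out of reach (and out of scope):
post-transcriptional regulation shifts absolute levels but has much less
effect on relative ordering.

## The model and its stages

Let `C` be the `m x n` count matrix (cells in rows). The pipeline is a
composition of four transparent stages, each exported on its own.

**Log-normalization** (`log_normalize`). `X_ij = ln(1 + C_ij s / Σ_j C_ij)`
with scale factor `s = 10 000`. Zeros map to zeros, so sparse input is
normalized without densification. A cell with zero total count is an error
(named by barcode), not a silent NaN.

**Truncated randomized SVD** (`randomized_svd`). A rank
`r = min(100, m - 1, n)` decomposition by Gaussian range projection with 2
subspace iterations and 10 oversampled dimensions. Power iterations and
oversampling are fixed rather than exposed prominently: with these values
the factorization agrees with an exact dense SVD to ~1e-14 relative error
whenever the sampled dimension reaches the ambient rank, which covers every
small-matrix use, and is spectrally accurate where it matters (the leading
components) on large matrices. The matrix is deliberately *not* centered:
rank selection below works on the standard deviations of the non-centered
principal components, and the reconstruction must live on the original
scale of `X`. The Gaussian test matrix is drawn from a caller-supplied seed
and the caller's RNG state is saved and restored, so fits are reproducible
and side-effect-free.

**Rank selection** (`select_rank`). The component standard deviations are
`σ_i / sqrt(m - 1)`. Their absolute consecutive drops are rounded to 2
decimals and run-length encoded; among runs with value at least
`delta = 0.01` and length at least `min_run = 2`, the smallest-valued run
wins (earliest on ties) and the selected rank is the 1-based position of
that run's first element, plus one. Three numerical choices deserve
comment:

* *Rounding before run-length encoding.* Floating-point drops are almost
  surely pairwise distinct, so without rounding every run has length one
  and no run could ever span "two or more" component pairs. Two decimals
  matches the 0.01 granularity of the threshold; the digit count is a
  parameter.
* *Absolute versus relative drops.* The drop is measured as an absolute
  difference of consecutive standard deviations by default; a relative
  (ratio-based) variant is available via `roc = "relative"` for users who
  think of the scree in proportional terms. The absolute form is the one
  the rest of the package is calibrated around.
* *Degenerate outcomes.* If no run qualifies (a flat spectrum), the full
  computed rank is used with a warning rather than silently returning
  something arbitrary; a selection below 2 is clamped to 2, because a
  rank-1 reconstruction makes every gene column an affine image of one
  vector and per-gene clustering degenerates.

**Reduced-rank reconstruction** (`reconstruct`). `X̂ = U_k Σ_k V_kᵀ`, the
Frobenius-optimal rank-`k` approximation; reconstruction error is
non-increasing in `k` (Eckart–Young), which the test suite checks against
an exact-SVD oracle.

**Clustered thresholding** (`threshold_gene`, driven by `select_k`).
Surface-protein expression distributions are characteristically bimodal —
an "off" sub-population plus one or more "on" modes. For each gene the
reconstructed column is clustered by *optimal* univariate k-means with the
cluster number chosen in 1–4; if more than one cluster is found, every cell
in the lowest-mean cluster is set to exactly 0 and all higher-cluster
values (including any negative reconstruction artifacts) are preserved
verbatim. If one cluster is found the column passes through untouched —
the estimator does not always threshold a gene, and it never applies a
common quantile across genes. An upper bound of four clusters accommodates
multimodality beyond simple on/off; the zeroed set for well-separated
bimodal genes is insensitive to this bound across roughly 3–15 (asserted
in the tests), so the choice is not load-bearing. Surviving negative values
can be clamped with `clamp_negatives = TRUE`; the default preserves them,
since they are informative about reconstruction quality and removing them
is irreversible.

## Optimal 1D k-means

The clustering subproblem is solved exactly, not by Lloyd-style iteration:
optimal one-dimensional clusters are intervals of the sorted values, so
dynamic programming over interval partitions finds the global minimum of
the within-cluster sum of squares, deterministically and with no dependence
on initial centers. The implementation (C++):

* aggregates duplicated values into weighted distinct values, which both
  guarantees that equal values are never split across a boundary and makes
  the contract `k ≤ #distinct` natural;
* computes interval costs in O(1) from prefix sums of `w x` and `w x²`
  accumulated in extended precision after shifting by the weighted mean
  (the shift leaves the objective unchanged and prevents catastrophic
  cancellation);
* fills each DP row by divide and conquer on the optimal split position,
  which is monotone in the right endpoint, for O(k u log u) over `u`
  distinct values.

The test suite pins the DP to an exhaustive enumeration over all interval
partitions for a thousand random inputs with ties and negatives.

**Choosing k.** The cluster count in `select_k` maximizes a
Gaussian-mixture BIC: each cluster contributes a Gaussian with its own mean
and variance and mixing weight `size/n`, `BIC(k) = 2 loglik − (3k − 1) ln n`.
Two guards make this robust on the degenerate inputs a reconstruction
produces. First, zero-variance clusters (repeated identical values) use a
floor variance of `(range · 1e-6)²`, which acts as a discrete-likelihood
special case: a mass of exactly equal values is overwhelming evidence for
its own cluster. Second, partitions containing a one-point cluster are
excluded from the comparison: under a per-cluster variance with a floor,
singletons otherwise make the likelihood arbitrarily large and the
criterion would always pick `kmax` — and a lone outlier cell is not an
expression mode. A practical consequence worth knowing: a unimodal Gaussian
cloud is *not* split, because splitting costs more in mixing weight than it
gains in per-cluster spread, which is exactly why un-thresholded
pass-through of unimodal genes works.

## What the synthetic generator emulates — and what it does not

`simulate_joint` produces paired counts and ADT with known truth:

* a planted low-rank log-mean — cell-type anchor vectors in a latent space
  of dimension `planted_rank` (default 8), small within-type jitter, Poisson
  (optionally negative-binomial) sampling; defaults 2 000 cells x 300 genes,
  4 types, 10 receptors, sized to run the full pipeline in a few seconds;
* bimodal receptors: each receptor is "on" in roughly half to all-but-one
  of the cell types, with exact protein level 0 in off cells and a
  per-cell lognormal level in on cells; the receptor transcript mean is
  `rna_capture` counts per unit protein (default 1 — single-digit counts,
  the dropout-dominated regime receptor transcripts actually occupy) plus
  an injected dropout rate (default 0.2);
* ADT monotone in protein: `Pois(5)` background plus `25 · protein` with
  multiplicative lognormal noise (`adt_noise`, default 0.3 on the log
  scale).

The capture parameter makes the generator's two regimes explicit. At
default (low) capture the raw transcript is a poor rank-proxy for the
protein and reduced-rank reconstruction recovers dropout zeros, which is
where the estimator earns its keep; at deep capture (`rna_capture = 10`,
no dropout, vanishing ADT noise) the raw transcript itself rank-tracks the
ADT at ρ ≥ 0.9 by construction of the monotone link — and in that regime a
smoother has little left to add, since per-cell protein variation
orthogonal to the latent space is exactly what a low-rank projection
discards. Both facts are asserted in the tests; passing them shows the
estimator behaves correctly *in the regime the generator models*. Real
data add ambient RNA, doublets, batch structure, UMI saturation and
cell-type proportions far more skewed than the generator's uniform draw;
nothing here speaks to those.

`simulate_spectrum` drives rank-selection tests directly: large mutually
distinct drops up to the planted elbow, a matched pair of 0.01 drops at the
boundary (the smallest qualifying run, whose position forces the selected
rank to equal the planted rank exactly), then sub-0.005 decay that rounds
to zero. With `signal_gap` below 0.01 every drop rounds to zero and the
fallback path is exercised.

## Evaluation utilities

ADT counts are normalized with the pseudocount centered log-ratio
transform, `ln(1 + x/g)` with `g` the geometric mean of `ln(1 + x)` along
the margin. The margin defaults to per-cell across antibodies and can be
switched to per-feature (`margin = "feature"`); both are in common use for
ADT and the choice is surfaced rather than hidden. Per-receptor agreement
is quantified by Spearman correlation by default — relative estimates are
only meaningful through their ranks — with Pearson and tie-adjusted
Kendall available. Receptors with constant estimate columns yield missing
correlations, never zeros. `proportion_best` summarizes competing methods
by the fraction of receptors each wins, splitting exact ties fractionally
so proportions always sum to one. Mean-squared/absolute error summaries
are deliberately not part of the default reports: they measure absolute
correspondence, which relative estimates do not promise.

## Problem sizes and determinism

The bundled tests and the acceptance script use the 2 000 x 300 synthetic
benchmark, matrices up to 80 x 60 against the exact-SVD oracle, a thousand
clustering inputs of length ≤ 12 against exhaustive enumeration, and one
hundred seeded spectra for the rank rule; the whole suite runs in well
under a minute. Every stochastic step flows through an explicit seed
argument, fits restore the caller's RNG state, and two fits with the same
seed are bit-identical — asserted as a contract, not aspirationally.

## Known limitations

* Estimates are relative; nothing calibrates them to copies-per-cell.
* A receptor regulated mostly post-transcriptionally will defeat any
  transcriptome-only estimator, this one included; on such genes even the
  sign of the correlation with protein can be wrong.
* Thresholding can only help when the "off" population is real; on a
  homogeneous population the BIC correctly finds one cluster and the
  method reduces to plain reduced-rank reconstruction.
* The scree-elbow rank rule is a heuristic. Its failure mode (a flat or
  cliff-free spectrum) is loud — fallback with a warning — but on such
  data the chosen rank, and hence the reconstruction, deserves scrutiny.
* Per-gene thresholding decisions are independent across genes by design;
  genes whose reconstructed values are constant pass through, and columns
  with fewer distinct values than `kmax` are handled by clamping, counted
  in the fit's `kmax_clamped` field.
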