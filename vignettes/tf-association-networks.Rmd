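---
title: "Inferring consensus TF association networks from binary binding profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring consensus TF association networks from binary binding profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfnet)
```

## The data model

The unit of analysis is a *sample*: one ChIP-seq profile of one TF in
one cell type. Peaks from all samples are merged into a single set of
disjoint genomic segments — two peaks merge exactly when they share at
least one base, so book-ended intervals (BED half-open coordinates,
`end == start` of the next) stay apart — and the compendium becomes a
binary matrix **X** with one row per merged segment and one column per
sample, `X[i, j] = 1` when sample *j* has a peak overlapping segment
*i*. Rows exist only where at least one sample bound.

Marginal association between two columns (Pearson correlation, which
for 0/1 data is the phi coefficient of the pair's 2×2 contingency table)
conflates direct interaction with everything else: shared upstream
regulators, cell-type block structure, and the growing sea of shared
zeros as compendia diversify. The package's premise is that *conditional*
dependence — association of a pair given all remaining samples — is the
better proxy for direct interaction, and that agreement among several
structurally different estimators of it is more trustworthy than any
single one.

## The four estimators

All four treat the binary columns as numeric observations of a jointly
distributed vector; this is a deliberate fidelity-over-purity choice —
the Gaussian-family machinery is applied to standardized 0/1 data
exactly as practitioners feed binary occupancy matrices to these tools.
Dequantifying assumptions are discussed under *Limitations*.

**Shrinkage partial correlation (`ggm_scores()`).** The sample
correlation matrix is shrunk toward the identity,
`R* = (1 − λ)R + λI`, with λ chosen by the analytic
variance-minimizing formula
`λ* = Σ_{i≠j} Var(r_ij) / Σ_{i≠j} r_ij²` (clipped to [0, 1]); the score
is `−Ω_ij/√(Ω_ii Ω_jj)` with `Ω = (R*)⁻¹`. The shrinkage guarantees a
well-conditioned inverse for p close to (or exceeding) what the row
count supports; at the row counts typical of peak unions λ* is tiny and
the estimate approaches the plain inverse-correlation partial
correlation — the test suite pins this case against a
residual-regression oracle at λ = 0.

**Graphical lasso (`glasso_fit()` / `glasso_scores()`).** Block
coordinate descent on
`log det Θ − tr(SΘ) − ρ Σ_{i≠j}|Θ_ij|`; each row/column update is a
lasso solved by coordinate descent. Only off-diagonal entries are
penalized, so at ρ = 0 the solution is exactly `S⁻¹` and the 2-variable
problem has the closed-form soft-threshold solution
`W₁₂ = sign(s)·max(|s| − ρ, 0)` — both are test oracles. Convergence is
declared when the largest fitted-covariance change in a sweep falls
below `tol × mean|S_offdiag|` (default `tol = 1e-6`); non-convergence at
`max_iter` (default 200) is an error, never a silent result. The default
ρ = 0.05 keeps the estimate sparse without emptying it at the package's
default problem sizes; because algorithms are compared at matched edge
*budgets* (below), the ranking, not the absolute sparsity, is what
matters.

**Stability-selection regression (`regression_scores()`).** Each
column in turn is the target of `n_resample` (default 100) lasso-path
fits, each on an independent half-sample of rows with predictor columns
rescaled by Uniform[α, 1] weights (default α = 0.2); the directed score
j→t is the fraction of fits where j is among the first `steps_L`
(default 5) variables to enter the path. Frequencies are in [0, 1] by
construction; the two directions are averaged. The lasso paths are
computed by glmnet; entry order is read off the lambda path.

**Bayesian-network skeleton (`bn_skeleton()`).** Greedy hill climbing
over DAGs (add / delete / reverse one arc, best improvement per sweep)
maximizing the decomposable BIC score for binary variables
(`loglik − log(n)/2 · 2^{|parents|}` per family), with seeded random
restarts (default 10) on top of the empty-graph start, a parent cap
(default 4) bounding family tables, and a guard cap on p. The best DAG's
arcs are stripped of direction. BIC was preferred over Bayesian
Dirichlet scores because it has no prior hyperparameter, and an
exhaustive-search oracle over all 543 DAGs on 4 nodes keeps the climber
honest in the test suite.

## Thresholding, consensus, benchmarking

A dependence matrix becomes a network via `select_edges()`: either an
absolute-score threshold, or an edge *budget* keeping the top-k pairs
(ties at the cut all included — relevant for the binary BN skeleton,
which can exceed its nominal budget). Because the four score scales are
incommensurable and per-algorithm significance thresholds are a
supplementary-level detail, the package's default policy is budget
calibration: every algorithm contributes the same number of top edges,
mirroring the construction of a correlation baseline "with a similar
number of edges". Diagonal entries are always ignored: a TF's influence
on itself is not modelled, so self-edges never appear.

`consensus_network()` keeps edges found by at least `min_support`
algorithms (default 3 of 4). The node universe is carried through
unchanged and isolated nodes are counted and removed only on request
(`prune_isolated()`), so reports can state both the sample universe and
the connected node count. Asymmetric matrices are symmetrized by
averaging the two directed scores before thresholding.

For benchmarking, a sample-level network collapses to unordered TF
pairs (`collapse_to_tf_pairs()`): a pair {A, B} is predicted iff some
edge joins a sample of A to a sample of B, A ≠ B, and both TFs belong
to the gold-standard universe. Confusion counts live over all C(u, 2)
pairs of that universe — this choice is forced by the arithmetic of the
published comparison table, whose rows all sum to C(56, 2) = 1540 with
96 positives — and precision/recall are reported as percentages. The
gold standard is a STRING-format table filtered at combined score ≥ 500;
the "binding" action keyword marks physical interactions and is carried
as an edge annotation, not as part of the positive definition.

## The synthetic-data generator

`planted_model()` + `simulate_binding()` provide the ground truth the
real data cannot: a latent Gaussian copula whose precision matrix has
unit diagonal and `−coupling_strength` at planted TF edges (plus
optional within-cell-type coupling), inverted, correlation-scaled, and
binarized at the `marginal_rate` Normal quantile. Partial correlations
of the latent field are elevated exactly at planted edges, which is the
estimand of the GGM-family estimators — this makes parameter recovery a
well-posed test, and is why the copula was chosen over, say, a logistic
conditional model. If the requested couplings break positive
definiteness the generator either rescales the off-diagonal block to
restore diagonal dominance (with a message) or errors, as requested.

Defaults define the study conditions used throughout the tests: 20 TFs
(one sample per TF), 30 planted edges, 2 000 segments, coupling 0.3,
marginal rate 0.3, two cell-type blocks. Rate 0.3 reflects that a
typical sample binds a minority of the union of all samples' sites;
2 000 rows is two to three orders of magnitude below a real peak union,
chosen so the full four-algorithm pipeline runs in tens of seconds —
`build_binding_matrix()` has a seeded row-subsampling hook for real
unions of ~5×10⁵ rows. All-zero rows are kept by the simulator (so
column marginals are exact) and disappear on the peaks round trip,
since a segment nobody binds is never written.

What the generator does *not* emulate: overlapping peaks across rows
(segments are tiled disjointly; merging is exercised on dedicated
fixtures), peak-height signal, motif content, genomic clustering of
binding sites, and the extreme zero-inflation of real compendia.
Passing recovery tests therefore demonstrate correctness of the
estimators on data matching their assumptions, not performance on real
ChIP-seq, where dependence is weaker and confounded.

## Numerical and design choices

* **Interval conventions.** BED coordinates are 0-based half-open
  throughout; "merge iff ≥ 1 bp shared" makes merging equivalent to
  non-empty half-open intersection. Interval algebra is delegated to
  GenomicRanges/IRanges (`reduce(min.gapwidth = 0)`,
  `findOverlaps(minoverlap = 1)`).
* **Clustering.** `cluster_samples()` delegates to `stats::hclust` on
  distance 1 − r with complete linkage — the routine this analysis
  conventionally uses; its deterministic (input-order) tie handling is
  accepted rather than re-implementing agglomeration for a bespoke
  tie-break, and the oracle test uses distinct-distance matrices where
  ties cannot arise.
* **Constant columns.** Undefined correlations become `NA` with a
  warning; such columns contribute no edges but remain in the node
  universe. `ggm_scores()` refuses constant columns outright.
* **Determinism.** Every stochastic stage (simulation, resampling,
  restarts, subsampling) takes an explicit seed; there is no hidden
  global RNG state contract. Identical seeds give bit-identical
  outputs.
* **TF names** are uppercased on ingest so source-specific casing
  unifies against gold-standard identifiers; cross-species identifier
  mapping is the user's responsibility via the `name_map` argument of
  `read_string_table()`.
* **Edge identity** is the unordered *sample* pair; collapse to TF
  pairs happens only in benchmarking, so networks over samples and
  benchmarks over TFs stay cleanly separated.
* **Rounding.** Published precision/recall tables mix truncation and
  rounding at two decimals; comparisons against printed values accept
  |Δ| ≤ 0.01 percentage points rather than guessing the formatter.

## Problem sizes in the test and acceptance runs

Oracle-equivalence tests run at p ≤ 6 (partial correlations, glasso)
and p = 4 with n = 400–500 over 20 seeded instances (BN exhaustive
search); the merge oracle uses 1 000 random intervals. Parameter
recovery runs the full pipeline at the generator defaults (20 TFs,
30 edges, 2 000 segments); each algorithm's edge-ranking AUC must beat
chance, the shrinkage GGM must exceed 0.9, and the consensus precision
at matched budgets must reach at least the median single-algorithm
precision. The end-to-end identity check simulates a noiseless study to
disk, rebuilds everything from files, and requires the true graph to
benchmark at exactly 100/100 against the noiseless gold standard.

## Limitations

Applying Gaussian-family estimators to binary data is an approximation:
scores are attenuated relative to the latent dependence, and the BN
hill climb is a local search whose restarts mitigate but do not remove
the risk of local optima at larger p. The consensus vote treats
algorithms as exchangeable although their errors are correlated (three
of four are Gaussian-family). Directionality, interaction mode
(activation vs repression), and signal strength are out of scope: the
network is undirected, unweighted, and built from binary occupancy
only.
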