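---
title: "Methods and design notes for scpipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for scpipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind each stage of the
pipeline, the parameters a user may want to move, the design decisions that
were genuinely open, and what the synthetic benchmark does and does not
demonstrate about real data.

## Input model

The pipeline operates on non-negative abundance values (FPKM or TPM) for
genes × cells, with every cell assigned to a sample — a library preparation
or batch. Abundances are floored at 0.01 before anything else, so
logarithms and correlations are always defined; the floor is idempotent and
configurable. Missing values are not allowed: an abundance matrix either
has a measurement or the quantifier reported zero, which the floor maps to
the minimal expression. The matrix is oriented genes-rows × cells-columns
throughout, so gene-wise operations are row-wise; gene identifiers are
case-sensitive and never remapped, keeping the pipeline species-agnostic.

## Pre-filtering

Two per-sample filters run before any analysis. The *expression filter*
keeps gene *i* in sample *s* when at least `n_min` cells express it at
`theta` or more. The defaults (θ = 5 FPKM in ≥ 2 cells) suit droplet-free,
plate- or chip-based data at moderate depth; `n_min = 1` is the right
choice when hunting rare cell types that would never recruit two cells.

The *specificity filter* uses the cell specificity index: min–max rescale
the gene's expression across the sample's q cells and average the
complement,
τ = Σⱼ(1 − xⱼ)/(q − 1). τ = 1 exactly when one cell carries all expression;
a constant gene is assigned τ = 0 by convention — the raw formula is 0/0
there, and a gene at the same level in every cell is maximally unselective,
which is what the filter exists to remove. Note that τ responds to the
*relative* configuration: a gene at 10 in one cell and 5 everywhere else
rescales to the single-spike pattern and scores τ = 1. The filter is
therefore applied together with the expression filter, and the default
τ ≥ 0.7 in *every* sample removes housekeeping-like profiles while keeping
genes restricted to a minority of cells.

Genes are reported in four sections: (1) passed both filters in every
sample — the retained set; (2) passed the expression filter everywhere but
failed specificity somewhere; (3) passed the expression filter in no
sample; (4) passed it in some samples only. The sections partition the gene
set, which the tests assert.

## Normalization and QC

Gene-level normalization is the per-sample z-score: each gene is centred
and scaled within each sample, which removes per-sample location/scale
differences (batch intensity) and is idempotent. z-scores are computed on
the floored abundance scale by default; a log2(x + 1) pre-transform is
available but not applied silently, since the abundance scale is what the
filters and fold-change metrics are defined on. Cell-level normalization
rescales every cell to a common trimmed mean (5% per tail by default; the
trim fraction is conventional rather than prescribed, and `trim = 0` gives
plain mean scaling).

QC summaries are diagnostic only: per-gene MA values
(M = log2 mean₁ − log2 mean₂, A = their average), matched quantiles of the
two samples' per-gene means, and Pearson correlation of log2(x + 1)
expression for every cross-sample cell pair with distance 1 − r. The
log2(x + 1) transform is this package's definition, chosen for variance
stabilization of abundance-scale data.

## Clustering

Cells are clustered agglomeratively on centered Pearson correlation
distance d = 1 − r with average linkage: the *trend* of expression across
genes, not its magnitude, is what distinguishes cell types, and average
linkage lets every cell contribute to the merge decision. d is kept on the
conventional [0, 2] scale rather than (1 − r)/2 — the demonstration
threshold of 0.5 is plausible on this scale, and the scale is configurable.
Ward linkage is tolerated with a warning when combined with a correlation
distance (a metric mismatch some users accept deliberately).

Three cut rules are supported: a height threshold, a fixed k, or — when
neither is given — the smallest merge height whose clustering contains at
most γ singleton clusters (γ = 0 by default). The γ-search guarantees
minimality: every lower cut has more than γ singletons. Note the γ-search
stops at the first admissible height, which may split off small
non-singleton clusters that a fixed threshold would absorb; for the planted
benchmark we therefore quote the demonstration setting, threshold = 0.5.
Cells are processed in lexicographic ID order so results cannot depend on
input order, and clusters are labelled C1, C2, … by decreasing size (ties
by smallest member ID).

Cluster significance is assessed by permutation. The statistic is the mean
within-cluster cell–cell correlation minus the mean between-cluster
correlation. The null permutes each gene's values across cells
independently — preserving every gene's marginal distribution while
destroying gene–gene and cell–cell structure — then re-clusters with
identical settings and recomputes the statistic. Both an upper-tail normal
approximation from the B null values (which can report p-values far below
1/B, as extreme observed separations warrant) and the empirical
(#{null ≥ obs} + 1)/(B + 1) are returned. A permuted clustering that
degenerates to a single cluster, or to all singletons under a threshold
cut, contributes a null statistic of 0 (no separation). The permutation
scheme is this package's construction; alternatives that preserve cell
totals would also be defensible.

## Differential expression

Each cluster is compared against all remaining cells, gene by gene,
one-tailed in the "greater in cluster" direction — the DE genes feed
marker, signature and network analyses, all of which concern
over-expression. Welch's unequal-variance t-test is used when **both**
groups exceed `min_parametric_n` = 5 cells; otherwise the Wilcoxon rank-sum
test, exact when the combined size is ≤ 20 without ties and
normal-approximated with tie correction otherwise. The Welch path is
vectorized over genes and tested against `t.test` per gene. When both
groups have zero variance the p-value is 0.5/0/1 by mean order, flagged
degenerate.

Benjamini–Hochberg correction is applied within each cluster's battery of
tests: per-cluster families match the per-cluster reporting of the
downstream analyses; a global family would only rescale all q-values
jointly. p-values are floored at 1e-300 before any −log transform.

## Cell-type enrichment and marker validation

Enrichment of a cluster's DE genes in a cell type's gene set is the
one-tailed Fisher exact test on the 2×2 membership table over a fixed
universe — by default the genes surviving pre-filtering, the only genes
eligible to be DE. Raw p (the primary ordering) and BH-adjusted q across
cell types within each cluster are both reported. Association tables
contribute a gene to a cell type only with positive experimental support at
p < 0.05 and, by default, no negative evidence.

Marker validation aggregates per-marker cell rankings with the robust
rank-aggregation ρ score: each of m markers ranks the N cells by descending
expression (average ranks on ties — unbiased for the AUC), and a cell's
score is the smallest binomial tail P(X ≥ k), X ~ Bin(m, r₍ₖ₎), over its
order statistics of normalized ranks. Only the ordering is consumed, so no
multiple-testing correction is applied to ρ; a Borda (mean-rank) fallback
is available. The AUC of the consensus ranking against the assigned cells
uses the rank-sum identity with half-credit for ties.

## Signature genes

Four metrics per (gene, cluster): *common* mc — expressed (≥ θ, the same
abundance threshold as the pre-filter, so one definition of "expressed"
serves the whole pipeline) in at least δ% of cluster cells, δ = 80 by
default to tolerate intra-cluster heterogeneity (δ = 100 for unified
clusters); *unique* mu — cluster mean at least α = 2 times the η = 0.85
quantile of the outside cells, the quantile tolerating a few outliers;
*test statistic* mt = −log p normalized by the cluster's maximum; and
*profile similarity* ms = (1 + ρ)/2 against the cluster's synthetic
reference profile. The reference is defined here as the cluster indicator
vector over all cells (1 inside, 0 outside): it encodes "selectively
expressed in this cluster", and a reference restricted to cluster cells
would be constant with undefined correlation. A constant gene profile gets
ρ = 0, ms = 0.5.

The metrics are combined by logistic regression trained on known markers
(positives) versus genes that are non-DE (p ≥ 0.05) with mc = mu = 0
(negatives), sampled to class balance under the caller's seed. Because a
marker training set is often linearly separable in these four features, the
likelihood alone has no maximum; a small ridge penalty (λ = 1e-4,
intercept unpenalized) guarantees a finite, reproducible optimum while
leaving the fit effectively maximum-likelihood away from separability. The
fit is Newton/IRLS with step halving and errors out with diagnostics rather
than silently returning a non-converged model. Candidate (cluster-DE)
genes are ranked by θ; a min–max normalized score is provided alongside.

Validation repeats r times: sample 80% of the cluster's cells, re-run the
whole signature prediction with the held-out cells excluded, take the top
`top_n` genes, and train one linear-kernel SVM per other cluster on 80% of
both clusters' cells restricted to those genes, scoring accuracy on the
held-out 20%. The contract is the accuracy estimate, not the classifier:
any linear margin classifier would do, and the SVM is used because it is
the conventional choice. `top_n` defaults to 100.

## Regulatory-network inference

Candidate TFs are catalog-verified genes either DE in the cluster
(p < 0.05) or commonly expressed there (mc = 1); candidate targets are
genes DE at p < 0.01. The TF catalog is a required user input — curated
TF/cofactor lists are resource-specific — and the simulator ships one for
its planted programs. Edges are scored by first-order conditional
dependence: for TF i and target j, every other candidate TF k is
conditioned on in the least-squares fit Xⱼ = m + αᵢⱼ|ₖXᵢ + αₖⱼ|ᵢXₖ + ε, and
the edge significance Sᵢⱼ is the *maximum* over k of the p-value for
αᵢⱼ|ₖ = 0 — an edge survives only if no single conditioning variable
explains it away, which makes retention under independence conservative
(below the nominal cutoff, as the null benchmark verifies). The
coefficient test is the standard two-sided regression t-test: the null
"α = 0" has unknown sign, and the coefficient's sign is reported per edge.
Conditioning TFs collinear with i (|r| > 1 − 1e-10) are skipped with a
warning; with fewer than 3 TFs, or all conditionings skipped, the marginal
regression p is used. Self-loops and target → TF feedback are excluded by
construction. In the full pipeline the inference runs on per-sample
z-scores: a multiplicative batch factor common to a sample's cells would
otherwise correlate all within-cluster profiles.

Importance metrics are computed on the undirected view of the network's
main connected component (size ties going to the component with the
lexicographically smallest node): the disruption metrics are defined
through connected components and mutual reachability, which are undirected
notions, while direction is retained in the edge-list output. Betweenness
counts ordered pairs and is reported unnormalized — only ranks are
consumed, and any consistent convention yields the same ranks. DFC, DCC
and DDC measure the fragmentation, lost reachability, and lengthened
geodesics of the residual graph after deleting a node, each normalized to
[0, 1]. TFs are ranked per metric in descending value with competition
(min) ranks — tied TFs share the smallest rank of their block, the
convention consistent with duplicated positions in averaged rankings — and
the final importance is the mean of the six ranks, ties again sharing a
position. Sensitivity (mean tie width) and relative power (Spearman
concordance of each metric's ranking with the consensus, normalized to
mean 1; a fully tied metric contributes 0 concordance) characterize each
metric's resolution and contribution.

## The synthetic benchmark

`simulate_cells()` draws log-normal abundances: background genes at
2^1 FPKM, per-cluster signature genes elevated by 3 log2-fold in their own
cluster, housekeeping genes high (2^6) and uniform, low-expression genes at
2^-2, all with log2-scale noise SD 0.3, split across two batches with
multiplicative scale factors 1 and 1.5 so that normalization has real work
to do. The default population is three clusters of 30 cells — sizes at
which both the Welch rule and the subsampling hold-outs are exercised.
Marker panels are the first five signatures per cluster; the association
table maps true signatures to synthetic cell types. Planted regulatory
programs add TFs (N(10, 2) within the cluster) and targets built from the
configured linear model. `simulate_regulatory_program()` is the
network-only counterpart with standard-normal TF profiles, 40 cells, unit
coefficients and noise SD 0.25 by default, plus decoy TFs.

The generator emulates the structure the methods assume — selectively
expressed signatures, unselective housekeeping genes, batch scale,
linear TF → target dependence. It deliberately does **not** model dropout
or zero inflation, transcript-length or depth biases, cell-cycle structure,
doublets, or nonlinear regulation. Passing benchmarks therefore
demonstrates correctness of the implementation under its own model
assumptions, not performance on droplet-based real data.

## Problem sizes and numerical choices

The test-suite and acceptance benchmarks run at: 90 cells × ~300 genes for
the end-to-end fixture; 10⁴ genes × 60 cells for null DE calibration;
500 TF–target pairs at 40 cells for null edge retention; 20 independent
seeds for network recovery; 200 random graphs of ≤ 12 nodes against
brute-force BFS/path-counting oracles; 20 subsampling repetitions (100 in
routine use). These sizes make every property measurable in seconds while
keeping binomial error small relative to the asserted margins.

Numerical conventions collected in one place: abundance floor 0.01;
p-values floored at 1e-300; constant genes get τ = 0, z = 0, ms = 0.5;
degenerate two-group tests return 0.5 with a flag; BH within cluster;
ridge λ = 1e-4; collinearity tolerance 1 − 1e-10; cluster labels and
rank ties broken lexicographically; all simulation and resampling functions
take explicit seeds and restore the caller's RNG state.

## Limitations

Hierarchical clustering with a global cut can fragment or merge
populations whose separation varies in scale; consensus or graph-based
clustering back-ends are out of scope here. The cell-type enrichment is
only as good as the association table supplied. The TRN captures linear,
first-order dependence within one cluster's cells: combinatorial or
nonlinear regulation, and directionality beyond the TF catalog's
asymmetry, are not identified. Integrating external evidence (ChIP-seq,
literature) to refine edges is outside this package's scope.
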