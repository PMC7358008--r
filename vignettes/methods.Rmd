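---
title: "Methods: a perinatal lung immune atlas pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a perinatal lung immune atlas pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lungatlas` implements the analysis chain used to build a single-cell
immune atlas of the developing mouse lung from Smart-seq2 data: eight
mice, one female and one male at each of four perinatal stages (E18.5,
P1, P7, P21), with on the order of 10^5–10^6 read pairs and thousands of
detected genes per cell. This vignette explains each stage's model and
assumptions, the parameters that matter, and the design decisions taken
where the procedure leaves room.

## Quality control and doublet accounting

Cells with fewer than 50,000 uniquely mapped reads or fewer than 400
detected genes are discarded (`filterCells()`). The thresholds are
exclusive for removal — a cell sitting exactly on a boundary is kept —
and a cell failing both filters increments both failure counters while
being removed once, so the `QCReport` dispositions partition the input
exactly.

Doublet removal operates at cluster level, replacing manual curation
with a reproducible rule (`flagDoubletClusters()`): a cluster is flagged
when at least half of its cells co-express (raw count > 0) the
pan-immune marker *Ptprc* together with at least one mutually exclusive
non-immune lineage marker (*Epcam* epithelial, *Cdh5* endothelial,
*Col6a2* mesenchymal), or when the cluster's mean CPM of any contaminant
marker exceeds that of the immune marker. The 0.5 co-expression fraction
is a documented default, not a measured quantity; both trigger
conditions are logged per cluster so a reviewer can audit each
exclusion. The pipeline clusters provisionally, removes flagged
clusters, and re-runs normalization, feature selection and clustering on
the cleaned matrix.

## Normalization and feature selection

Counts are normalized to counts per million per cell; displayed and
PCA-input values are `log10(cpm + 0.1)`, so a zero count maps to exactly
−1. The pseudocount of 0.1 CPM is fixed throughout the package
(fold-change shrinkage uses the same 0.1).

Highly variable genes are chosen by the Fano factor (variance/mean), the
natural overdispersion statistic for count data, computed **per mouse**:
within each replicate with at least 5 cells, genes are ranked by
decreasing Fano factor of their CPM values, a gene's *support* is the
number of mice in which it ranks within the top `high_rank_cutoff`
(default 1000), and the 500 selected features are ordered by support,
then mean rank, then symbol. Requiring high variability *in most mice*
prevents a single animal's technical noise from defining the feature
set. Two knobs are open by construction and config-exposed: the rank
cutoff that operationalizes "high", and the scale on which the Fano
factor is computed. We compute it on CPM (normalization precedes
selection in the pipeline order); computing it on raw counts is a
one-line change and gives closely related rankings at Smart-seq2 depth.

`fanoFeatureSelect(excludeGenes = ...)` can blacklist genes regardless
of rank. This matters for trajectory analysis (below), where cell-cycle
genes otherwise dominate the subset geometry.

PCA uses the top 25 components of the centered (not variance-scaled)
log-CPM matrix over the selected genes, with a deterministic solver and
a fixed sign convention (the largest-magnitude loading of each component
is positive), so the coordinates — and everything downstream of them —
are exactly reproducible.

## Clustering, embedding, annotation

The cell graph is a symmetrized (edge-union), unweighted k-nearest
neighbor graph in PC space, k = 15 by default; neighbor ties are broken
by ascending cell index so the graph is deterministic. The kNN search is
done exactly over the full distance matrix — at the few-thousand-cell
scale this package targets, exactness and a controlled tie-break are
worth more than the speed of an approximate index.

Communities come from Leiden modularity optimization (via `igraph`).
The resolution was calibrated once on the default synthetic design so
that the planted population count is recovered, giving the default of
0.4, and is stored in the pipeline configuration; labels are relabeled
to contiguous integers from 0 in decreasing size order, making
clusterings comparable across runs. t-SNE is initialized from the first
two (rescaled) principal components rather than at random, which pins
the global geometry across seeds — important because the batch check
below measures distances in this embedding.

Cluster annotation scores each (cluster, type) pair as the mean
expressing fraction of the type's marker genes (direction-signed);
a cluster whose best score is below 0.25 stays "unassigned", and exact
ties resolve by panel order with a logged warning. "Expressing" means
raw count > 0 — the same detection rule that sizes dot-plot dots.

## The replicate batch check

For every (cell type, timepoint) stratum, 100 cell pairs are drawn from
within single mice and 100 pairs across the two mice of the stage, and
their Euclidean distances in the t-SNE plane are compared. Pairs are
sampled uniformly over the respective pair sets with replacement (small
strata do not have 100 distinct pairs); strata without at least two mice
of two cells each are reported as `insufficient_cells` rather than
tested. Restricting different-mouse pairs to a single timepoint matches
the question actually asked — do the replicate mice at each stage agree?

The reported statistic is the two-sided KS sup-difference between the
two distance CDFs. The *decision*, however, is one-sided: mouse-to-mouse
batch structure can only make different-mouse pairs *longer*, so the
p-value is the Smirnov tail `exp(-2 n_eff D+^2)` of the one-sided
statistic `D+ = sup(F_same − F_diff)`. A two-sided test combined with a
post-hoc direction filter would reject at only about half the nominal
rate under exchangeable mice (the direction is a coin flip conditional
on significance); the one-sided form keeps the stratum-level type-I
error at the nominal α = 0.05, which the test suite verifies over 50
simulated null replicates. α and the pair count are parameters;
distances can optionally be measured in PC space instead.

## KS differential expression

Marker ranking is a per-gene two-sample Kolmogorov–Smirnov comparison of
the target cluster against all other cells, on CPM values. The statistic
is computed from the pooled sorted sample, evaluating the CDF gap only
at distinct values so ties (zeros above all) are handled exactly; it is
invariant under strictly monotone transforms, so CPM versus log-CPM is
immaterial. P-values use the exact conditional-on-ties distribution
(`stats::psmirnov`) when the smaller group has ≤ 25 cells — the regime
of the smallest clusters — and the asymptotic Kolmogorov tail otherwise.
Published per-cluster tables floor extreme p-values at machine-level
constants; we report our computed values and do not attempt to bit-match
another implementation's flooring. The table schema is (gene, statistic,
p-value, log2 fold change), sorted by decreasing statistic with
deterministic tie-breaks, truncated to the top N (35 for the headline
tables, 100 for pathway input), keeping only positive fold changes in
one-vs-rest mode.

## Graph smoothing

For visualizing genes with low or noisy expression, the CPM matrix is
averaged over the clustering kNN graph: one round replaces each cell's
value by the mean of itself and its neighbors (row-normalized `A + I`
with binary weights), and the default two rounds reach exactly
second-order neighbors — a deliberately simple diffusion that reuses the
very graph the clustering and embedding are built on. Neighborhood sums
are divided once rather than pre-normalizing the operator, keeping
constant vectors exact fixed points. Smoothed values are stored in
separate assays and used for display only; clustering and differential
expression always see unsmoothed data.

## Pseudotime, potential, attractors

Pseudotime is diffusion-based: on the kNN graph of the cells of
interest, the symmetrized transition operator is eigendecomposed and
each cell's pseudotime is its diffusion distance to a root cell,
`sum_i (lambda_i / (1 - lambda_i))^2 (psi_i(x) - psi_i(root))^2`,
min-max scaled to [0, 1]. Cells disconnected from the root's component
are flagged `NA` rather than silently placed. The root is the cell with
the highest mean log expression of a configurable early-marker set — a
reproducible stand-in for picking the starting cell by eye.

`pseudotimeOnSubset()` encodes the practice that matters here: within a
single population, re-select features on the subset and exclude
cell-cycle genes (*Mki67*, *Mcm5* by default) before PCA. Proliferation
is a strong, near-binary transcriptional axis; left in the feature set
it becomes the leading principal component of any macrophage subset and
either splits the diffusion graph or contaminates the ordering. With it
excluded, the latent maturation axis is the dominant geometry.

The scalar-potential view lays a 50 × 50 grid over the embedding's
bounding box; a node is populated when a cell lies within 1.5 grid
spacings, and its potential is the inverse-distance-weighted mean of the
pseudotimes of cells in that radius (an exact hit contributes its value
directly). Local maxima — attractor states — are plateaus of populated
nodes (potential equal up to a 1e-9 relative tolerance, 8-connected)
whose populated border is strictly lower; a constant patch therefore
contains no maximum, and a plateau counts once, represented by its
lowest-index node. The gradient uses central differences where both
axis neighbors are populated, one-sided differences otherwise, and is
exact for affine potentials at interior nodes; arrows point uphill,
toward increasing pseudotime, so attractors are sinks of the reversed
field. All grid parameters (nx, ny, radius factor, interpolation
scheme) are unconstrained choices and exposed as arguments. The scalar
potential assumes a curl-free field: a genuinely rotational
developmental flow (e.g. a self-renewing population) cannot be
represented, and this package deliberately does not implement RNA
velocity to address it.

## Abundance, proliferation, repertoire

Composition tables report counts and percentages per (timepoint, type),
with the denominator either all annotated immune cells or a restricted
compartment (e.g. percent of macrophage/monocyte cells); unassigned
cells are tabulated but excluded from denominators. Displayed
percentages come with log10 values, matching the log-scale abundance
panels this kind of atlas uses. Proliferation is detection-based: a
macrophage/monocyte cell is proliferative when at least one of *Mki67*,
*Mcm5* has a nonzero count — an explicit, scale-invariant stand-in for a
visual call, with the marker set and the required count configurable.
B-cell receptor germline identity is consumed as a per-cell table
(contig assembly is upstream of this package); the package computes the
cumulative identity curves per locus and flags somatic hypermutation
when the median identity drops below 0.98.

## The synthetic atlas: what it emulates, what it does not

`generateAtlas()` draws negative-binomial (gamma-Poisson) counts with
gene-level dispersion 0.1 and log-normal library sizes (median 3 × 10^5,
sdlog 0.4), for 8 mice × 250 cells across the four stages. Fifteen
populations follow an editable composition table that encodes the
developmental narrative — Mac I is 80% of the macrophage/monocyte
compartment at E18.5 and collapses after birth, Mac II peaks at P1,
lymphocytes expand to dominate by P21 — with every population floored at
2% per stage so that its markers remain observable in each replicate
(a hard zero would make stage-specific markers invisible to the
per-mouse Fano criterion, which is a real failure mode of per-replicate
selection, not an artifact of the simulation). Each population carries
20 markers at ~1500-fold contrast over background (well above the
minimal 8-fold the generator guarantees), the five macrophage
populations share a *Cd68* analogue, doublets sum two parent draws plus
an *Epcam*/*Cdh5*/*Col6a2* block, low-depth cells fall below the
50,000-read filter, Mac V carries a 12-gene maturation program driven by
a latent time drawn uniformly within every mouse, and macrophage
proliferation fractions decline 0.6 → 0.4 → 0.2 → 0.1 across the four
stages. A per-mouse log-normal expression shift (`mouseEffectSd`,
default 0) injects replicate batch structure on demand.

The generator reproduces the statistical structure the pipeline's
guarantees depend on — overdispersed counts, marker-driven populations,
compositional change, replicate structure, doublets, depth failures —
but not everything about real Smart-seq2 data: gene–gene correlation
beyond population membership, amplification-induced zero inflation,
transcript-length bias, continuous mixtures between lineages, and
realistic gene counts (2000 genes rather than ~20,000) are absent.
Passing tests therefore demonstrate correctness and calibration of the
algorithms under the designed conditions, not performance on any
particular real dataset.

## Problem sizes and determinism

The test suite runs the full pipeline on the default 2000-cell atlas for
five seeds, and calibrates the batch test on 50 replicates of a reduced
design (2 populations × 120 cells per mouse, 300 genes) chosen so each
stratum holds ~120 cells — large enough that the 100 sampled pairs are
not dominated by shared cells. Every stochastic step (generation,
Leiden, t-SNE, pair sampling) takes an explicit seed and restores the
caller's RNG state, so identical inputs and seeds give bit-identical
results end to end.
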