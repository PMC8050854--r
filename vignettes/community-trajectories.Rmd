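---
title: "Multilayer community trajectories: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer community trajectories: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commtraj)
```

## The model

commtraj stratifies patients of a rare disease (the motivating application
is medulloblastoma, with its WNT / SHH / Group 3 / Group 4 reference
subgroups) from a general-purpose multiplex gene network — a set of named
undirected layers (protein interactions, drug targets, pathway
co-membership, variant-disease links, metabolic reactions, ...) sharing one
gene universe — plus per-patient altered-gene lists.

The quality function is the multiplex modularity under a single shared
partition $c$:

$$Q(c;\gamma) \;=\; \sum_{s}\frac{1}{2m_s}\sum_{ij}
\left[A^{(s)}_{ij}-\gamma\,\frac{k^{(s)}_i k^{(s)}_j}{2m_s}\right]
\delta(c_i,c_j),$$

the sum over layers of each layer's Newman–Girvan modularity, with one
resolution parameter $\gamma$ multiplying the configuration-model null term
identically in every layer. Layers are summed, not averaged (a $1/L$
scaling would not change the optima), and a gene absent from a layer has
degree zero there. `louvain_multiplex()` maximizes $Q$ greedily: seeded
random node order, each node moves to the neighboring community with the
largest positive gain (ties to the smallest community id), aggregation of
all layers over the same super-nodes, iterated until no move improves $Q$
by more than `1e-12`. Everything is deterministic given the seed.

Sweeping $\gamma$ over a grid (`resolution_sweep()`) and recording, per
gene, the community it occupies at every grid point yields the gene's
*community trajectory*. Two genes are compared by the trajectory Hamming
distance $d_H$: the number of grid positions at which they occupy different
communities. $d_H$ is an integer count on the scale of the grid length (a
normalized variant sits behind `normalize = TRUE`), judged by
co-membership, hence invariant to community relabeling; it is a
pseudometric (symmetric, zero diagonal, triangle inequality).

## Patient stratification

For each patient, the altered genes are grouped by complete-linkage
clustering of their pairwise $d_H$, cut at height $\theta$; at $\theta = 0$
the groups are exactly the classes of genes that are *never* separated
along the sweep. Groups of size $s$ with $s_{\min} \le s \le \lambda$
survive; the union of surviving groups is the patient's minimal gene set.
$\theta$ measures trajectory persistence, $\lambda$ caps how large an
association may be and still count as specific. $s_{\min}$ defaults to 2:
a selected gene must be tightly associated with at least one co-member, so
singletons carry no association evidence and are excluded (set
`smin = 1` to keep them).

Patient similarity is the Jaccard index of the selected sets (two empty
sets are defined as similarity 1, exactly one empty as 0). Patients are
agglomerated by Ward linkage on $1-J$ using the squared-distance
Lance–Williams update (`ward.D2`), the convention that remains well behaved
on non-Euclidean Jaccard distances. The number of clusters is chosen by
running PAM (k-medoids, deterministic BUILD+SWAP) for $k = 2..k_{\max}$ on
the same distances and maximizing the average silhouette width, ties toward
the smallest $k$; the Ward tree is then cut at that $k$ (Fig-style
presentation of tree plus PAM-suggested boxes; `method = "pam"` returns the
PAM clusters themselves).

`score_clustering()` maps every cluster to its majority reference label
(lexicographic tie-break), which deliberately allows more clusters than
reference subgroups — a mixed cluster simply maps to its majority subgroup.
Two accuracies are reported, because the averaging convention behind a
printed cohort accuracy is often not recoverable: the micro accuracy
(percent of patients whose mapped label matches their reference) and the
macro accuracy (mean per-subgroup recall). The Matthews correlation
coefficient uses the multiclass (Gorodkin) form on the mapped confusion
table and is defined as 0 when its denominator vanishes.
`optimize_parameters()` scans a $(\theta,\lambda)$ grid, scores every pair,
and breaks accuracy ties by larger MCC, then fewer selected genes per
patient, then smaller $\lambda$, then smaller $\theta$ — preferring the
most parsimonious optimum. Held-out patients (`classify_heldout()`) are
selected at the trained optimum and inherit the cluster of their most
Jaccard-similar training patient, with the full ranking returned; an empty
held-out selection is an explicit "unclassifiable" outcome, never a silent
assignment.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| resolution grid | `1:20` | dimensionless $\gamma$ | spans one-community to fragmented regimes (below) |
| $\theta$ grid | `0:3` | grid steps | persistence tolerance; 0 = never separated |
| $\lambda$ grid | `2:10` | genes | association size cap around the canonical 6 |
| $s_{\min}$ | 2 | genes | excludes singletons (no association evidence) |
| $k_{\max}$ | 8 | clusters | PAM search bound, twice the 4 reference subgroups |
| shuffles | 10000 | replicates | null distribution of accuracy |
| bootstrap $B$ | 1000 | replicates/scale | multiscale bootstrap |
| Monte Carlo $M$ | 999 | replicates | empirical p resolution 0.001 |

The default grid deserves a note. With the default synthetic network
(below), $\gamma \in [1, 4]$ resolves the whole graph into coarse modules,
$\gamma \in [5, 14]$ into the planted submodules, and $\gamma \in [15, 20]$
fragments submodules into small persistent gene groups — the substrate of
the $(\theta,\lambda)$ selection. Beyond $\gamma \approx 25$ the null term
dominates every pairwise tie and partitions collapse to singletons, after
which trajectories carry no further information and $\theta = 0$ classes
would empty; the default therefore stops at 20. Real networks with other
density scales need other grids, which is why the grid is a first-class
argument everywhere.

## The synthetic study

`simulate_multiplex()` plants two nested scales — 4 modules × 3 submodules
over 300 genes, 3 layers — with independent Bernoulli edges at
`p_fine = 0.3` (within submodule), `p_coarse = 0.05` (within module) and
`p_background = 0.003`, and silences each submodule per layer with
probability 0.1 (its fine edges degrade to coarse) to create layer
heterogeneity. These densities give mean degrees near 10 and hence the
three-regime sweep described above; they are the package's reference
conditions and are not adjusted per analysis. `simulate_cohort()` assigns
two disjoint signature submodules to each of 4 subgroups (8 patients each),
keeps each signature gene with probability 0.9, and adds 40 background
genes drawn from the non-signature pool.

What the generator emulates: multiscale community structure, layer
heterogeneity, subgroup-specific signatures diluted by per-patient noise.
What it does not emulate: heavy-tailed degree distributions, correlated
layers, identifier noise, or biologically structured backgrounds. Passing
the planted-recovery checks therefore demonstrates that the machinery
recovers the structure it models — not that any particular real cohort
will stratify at a given accuracy.

## Robustness and significance procedures

*Shuffle null.* `shuffle_cohort()` permutes the pooled patient–gene
incidence by a seeded permutation with pairwise-swap repair of
within-patient duplicates, preserving both marginals exactly (each
patient's count, each gene's frequency). `shuffle_analysis()` holds
$(\theta, \lambda)$ fixed at the trained optimum across replicates — the
fixed-parameter reading of a shuffled-cohort analysis; re-optimizing per
replicate can be composed manually from the exported pieces. A replicate
whose selections are all empty scores accuracy 0 and is flagged rather than
dropped.

*Recursive exclusion.* `iterative_exclusion()` re-optimizes, removes each
patient's selected genes from that patient only, and repeats until a
selection empties, a patient would empty, or accuracy reaches 0. Removed
sets are disjoint per patient across iterations by construction.

*Multiscale bootstrap.* `au_pvalues()` resamples feature columns of the
binary patients × selected-genes incidence at scales $r \in
\{0.5,\dots,1.4\}$, recomputes Jaccard distances and the Ward tree, and
records per original node the bootstrap probability $BP(r)$ of its member
set. The approximately unbiased value comes from the weighted
least-squares fit $\Phi^{-1}(1-BP(r)) \approx v\sqrt{r}+c/\sqrt{r}$ (probit
scale, binomial delta-method weights), $AU = 1-\Phi(v-c)$; degenerate nodes
(BP all 0 or all 1) clamp to 0 or 1.

*Monte Carlo node significance.* The published pipelines this package
parallels report an empirical and a Gaussian approximate p per cluster; the
statistic behind those outputs is not recoverable, so
`monte_carlo_pvalues()` exposes the same outputs through an explicit,
documented construction of this package: per node (≥ 3 members), embed the
node's sub-distance matrix by classical MDS, score the node's two children
by the between- over total-dispersion ratio, and compare against $M$
Gaussian datasets *conditioned on the embedded sample mean and covariance*
(Ward-split in two, same statistic). The conditioning matters: a plain
parametric bootstrap from an estimated covariance doubles the apparent
anisotropy and makes the p values conservative; with conditioning the
empirical p is approximately uniform on structureless Gaussian data (a
property the test suite checks by Kolmogorov–Smirnov). Empirical p uses the
add-one rule, so it is never 0 and never below $1/(M+1)$; nodes with fewer
than 3 members are reported as absent rather than 1.

*Link enrichment.* `neat_test()` scores the edges between a patient's
minimal gene set (A) and an entity's gene set (B, e.g. a drug's targets)
within one layer against a degree-preserving null: with $m$ layer edges and
$d_A, d_B$ summed degrees, the cross-link count is
$\mathrm{Hypergeometric}(2m, d_B, d_A)$, expectation $d_A d_B / 2m$,
one-sided upper tail (over-representation only). Overlapping A and B is
resolved by trimming B (with a warning) by default, or an error in strict
mode. Benjamini–Hochberg correction is applied per patient within each
layer across entities; an entity is *consensus* in a cluster when adjusted
p ≤ α for every patient of the cluster and *unique* when consensus in
exactly one cluster.

## Numerical choices and conventions

- Louvain move tolerance `1e-12`; ties to the smallest community id; the
  recorded quality trace after each pass is non-decreasing by construction.
- Partitions are canonicalized by first-node appearance, so community ids
  are stable, contiguous and comparable across writers and readers.
- Community identity for birth/death/resurgence events is exact member-set
  equality; a community still present at the last grid point does not count
  a terminal death by default (`count_terminal = TRUE` for the other
  convention). Either way deaths − resurgences ∈ {0, 1} per community.
- Weighted edges are accepted by the readers but the default pipeline
  treats layers as unweighted (`weighted = TRUE` to opt in).
- Gene identifiers are opaque strings; no identifier mapping is attempted.
- Degenerate guards: zero-edge layers are an error (the layer modularity is
  undefined); empty patient gene sets are an error at construction; an
  all-empty selection across a whole grid is an error naming the condition.

## Problem sizes used by the checks

The test suite and the acceptance script run the full default synthetic
study (300 genes, 3 layers, grid 1:20, 32 patients), 50 shuffle
replicates, $B = 500$ bootstrap replicates on a 12 × 30 block design,
$M \in \{99, 199\}$ Monte Carlo replicates over 8 calibration datasets, and
200 degree-preserving rewirings for the enrichment calibration. These sizes
were chosen to exercise every regime of the method at desk scale; all
replicate counts are arguments, and the defaults above are larger.

## Limitations

- The multiplex model shares one partition across layers; there is no
  inter-layer coupling term and no overlapping communities.
- Trajectory coherence depends on the seeded determinism of the sweep;
  near-degenerate modularity landscapes can still flip marginal genes
  between fragments at adjacent resolutions, which is what $\theta > 0$
  absorbs.
- The Monte Carlo separation statistic is this package's construction (see
  above); its p values are comparable within an analysis, and calibrated on
  Gaussian nulls, but are not the output of any published implementation.
- Printed cohort-scale numbers from real studies depend on their full
  networks and patient data and are out of reach of the bundled synthetic
  studies by design.
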