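# commtraj

Patient stratification from **multilayer community trajectories** in
multiplex gene networks.

Rare-disease cohorts are small compared with the dimensionality of their
multi-omics profiles, so clustering patients directly on their altered-gene
lists is fragile. commtraj takes the opposite route: it reads structure out
of a general-purpose multiplex network — layers such as protein
interactions, drug targets, pathways, variant–disease links and metabolic
reactions over one gene universe — and uses that structure to compress each
patient to a *minimal set* of genes whose network behavior is distinctive,
then clusters patients on those minimal sets. The motivating application is
medulloblastoma and its WNT / SHH / Group 3 / Group 4 reference subgroups.

## The method

1. **Multiplex modularity.** Communities are detected under a single
   partition shared by all layers, maximizing

   $$Q(c;\gamma)=\sum_s \frac{1}{2m_s}\sum_{ij}
   \Big[A^{(s)}_{ij}-\gamma\frac{k^{(s)}_i k^{(s)}_j}{2m_s}\Big]
   \delta(c_i,c_j)$$

   with a seeded multiplex Louvain (`louvain_multiplex()`).
2. **Trajectories.** Sweeping the resolution $\gamma$ over a grid
   (`resolution_sweep()`) gives every gene a trajectory — the sequence of
   communities it visits. Trajectories are compared by the Hamming distance
   $d_H$ (number of grid positions at which two genes part ways), and
   communities can be tracked through birth, death and resurgence events
   (`community_events()`).
3. **Minimal gene sets.** Per patient, altered genes are grouped by
   complete linkage on $d_H$ cut at height $\theta$; groups of size
   $\le\lambda$ (and $\ge s_{\min}=2$) survive. $\theta=0$ keeps only genes
   that *never* separate across the sweep.
4. **Stratification.** Jaccard similarity of the minimal sets → Ward
   (`ward.D2`) tree → cluster count chosen by PAM average silhouette →
   accuracy / macro accuracy / multiclass MCC against reference subgroups,
   optimized over a $(\theta,\lambda)$ grid (`optimize_parameters()`), with
   Jaccard nearest-neighbor classification of held-out patients.
5. **Robustness and significance.** Marginal-preserving cohort shuffles,
   recursive gene exclusion, multiscale-bootstrap AU values, Monte Carlo
   empirical/Gaussian node p values, and a NEAT-style hypergeometric
   link-enrichment test per layer entity with BH correction and per-cluster
   consensus/unique calls.

A planted-structure generator (`simulate_multiplex()`,
`simulate_cohort()`) provides nested multiscale networks and cohorts with
subgroup signatures, so the whole pipeline is exercisable without any
external data.

## Worked example

```r
library(commtraj)

sim  <- simulate_multiplex(seed = 1)          # 300 genes, 4x3 submodules, 3 layers
sim$network
#> A multiplex network: 300 nodes, 3 layer(s)
#>   layer1: 1541 edges
#>   layer2: 1508 edges
#>   layer3: 1582 edges

prof <- resolution_sweep(sim$network, seed = 1001)
prof
#> A resolution profile: 20 resolutions over 300 nodes; communities 4-183

traj <- build_trajectories(prof)
glance(community_events(prof))
#> # A tibble: 1 x 4
#>   communities births deaths resurgences
#> 1         610    798    615         188

co   <- simulate_cohort(sim$truth, seed = 2001)   # 4 subgroups x 8 patients
co   <- restrict_to_network(co, rownames(traj))
scan <- optimize_parameters(co, traj)
scan
#> A parameter scan over 36 (theta, lambda) pairs
#> best: theta = 0, lambda = 2 -> accuracy 100.00%, MCC 1.000, k = 4
glance(scan)
#> # A tibble: 1 x 7
#>   theta lambda accuracy macro_accuracy   mcc     k avg_genes
#> 1     0      2      100            100     1     4      11.9

null <- shuffle_analysis(co, traj, scan$best, n_replicates = 20, seed = 3001)
null
#> Shuffle null (N = 20, theta = 0, lambda = 2): mean accuracy 47.34% (SD 6.27)
```

Reading: the sweep resolves the planted hierarchy (4 coarse modules at
$\gamma=1$ up to 183 communities at $\gamma=20$); the optimizer finds that
genes which never separate ($\theta=0$) in small groups suffice to
recover all four planted subgroups exactly (accuracy 100, MCC 1, four
clusters), compressing each patient to ~12 genes; shuffling the cohort
while preserving every marginal collapses the accuracy to ~47%, i.e. the
stratification rests on the planted gene–subgroup association, not on set
sizes.

`autoplot()` methods are available for parameter scans (accuracy vs.
selection size), shuffle nulls and resolution profiles; `tidy()` and
`glance()` return tibbles for all result objects. A thin command-line
front end over the same functions ships at `inst/cli/commtraj.R`
(subcommands `simulate`, `sweep`, `trajectories`, `optimize`, `stratify`,
`classify`, `shuffle`, `exclude`, `significance`, `enrich`), and
`run_pipeline()` drives the same stages from R with a JSON manifest per
stage.

## Documentation

The methods vignette (`vignettes/community-trajectories.Rmd`) documents the
model, every tunable parameter with units and defaults, the synthetic
generator's scope, the numerical conventions, and known limitations.
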