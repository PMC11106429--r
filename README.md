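# amonet

Community analysis for amplicon OTU count tables: rarefaction and alpha
diversity, Bray–Curtis ordination with ANOSIM, and Spearman-thresholded
co-occurrence networks with topology metrics and Zi–Pi node-role
classification. The package grew out of the analysis chain used for soil
ammonia-oxidizer (amoA) communities under contrasting irrigation
treatments, but nothing in it is specific to that system: any
OTU-by-sample table with a sample-to-group mapping works.

It is aimed at microbial ecologists who want the standard downstream
statistics of an amplicon survey as plain, seeded, testable R functions —
plus a ground-truthed simulator to verify that the whole chain actually
recovers known structure before it is trusted on real data.

## What it computes

* **Alpha diversity** after rarefying every sample to a common depth:
  observed richness, Shannon entropy `H = -Σ p_i ln p_i`, and Chao1
  `S_obs + F1²/(2F2)` (bias-corrected form when `F2 = 0`).
* **Beta diversity**: Bray–Curtis dissimilarity
  `d = Σ|x_i − y_i| / Σ(x_i + y_i)`, classical PCoA (double centering +
  eigendecomposition, negative eigenvalues reported), and the ANOSIM
  statistic `R = (r̄_B − r̄_W)/(M/4)` with a seeded permutation p-value.
* **Co-occurrence networks**: pairwise Spearman ρ with t-approximation
  p-values; edges where `|ρ| > 0.7` and `p < 0.01` (both strict,
  configurable); node/edge counts, average degree `2E/N`, edge density
  `2E/(N(N−1))`, linkage density `E/N`, average path length, clustering
  coefficient; Louvain modules and Newman modularity Q; Guimerà–Amaral
  `Zi` (within-module degree z-score) and `Pi` (participation
  coefficient), with roles from the 2.5 / 0.62 grid.
* **Synthetic communities**: negative-binomial counts via a Gaussian
  copula with planted correlated OTU blocks and group effects, so every
  stage above can be scored against known truth
  (`ground_truth_edges()`, `edge_jaccard()`).

## Worked example

```r
library(amonet)

cfg <- simulation_config(n_otus = 100, groups = c("FP", "DI", "MF"),
                         replicates_per_group = 10,
                         modules = planted_modules(rep(10, 2), 0.9),
                         seed = 42)
ds <- generate_dataset(cfg)

rt <- rarefy(ds$table, min(colSums(ds$table)), seed = 1)
head(alpha_diversity(rt), 3)
#>   sample_id depth observed_otus  shannon chao1
#> 1      FP.1 39358           100 3.226608 100.5
#> 2      FP.2 39358           100 3.649143 100.0
#> 3      FP.3 39358            99 3.386244  99.0

anosim(bray_curtis(rt), ds$metadata, n_permutations = 999, seed = 2)
#> ANOSIM: R = 0.5015, p = 0.001 (999 permutations)

net <- build_network(spearman_matrix(rt), rho_min = 0.7, p_max = 0.01)
mods <- detect_modules(net, seed = 3)
topology(net, mods)
#> Network topology
#>   nodes                            22
#>   edges                            86
#>   edge_density                     0.3723
#>   average_degree                   7.8182
#>   ...
#>   modularity                       0.5097
#>   n_modules                        3

edge_jaccard(network_edges(net), ground_truth_edges(ds))
#> [1] 0.9340659
```

Reading the numbers: the three simulated treatments share the same OTU
pool, so rarefied richness is flat at ~100 OTUs, but the planted group
effect separates community composition (ANOSIM R = 0.50 at p = 0.001, the
smallest p that 999 permutations can produce). The network stage recovers
the two planted 10-OTU correlation blocks almost perfectly: 93% of
inferred edges coincide with planted pairs (Jaccard 0.93), and the edges
fall into modules with Q = 0.51 — the signature of two dense cliques.
`zi_pi()` then labels each node's role; dense uniform cliques have zero
within-degree spread, so their members are all `peripheral`.

## The analysis workflow

`analysis/` holds numbered drivers that run the whole chain on a simulated
three-treatment survey and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # survey + ground truth
Rscript analysis/02_alpha_diversity.R # rarefy, Shannon/Chao1 per sample
Rscript analysis/03_beta_ordination.R # Bray-Curtis, PCoA, ANOSIM
Rscript analysis/04_network.R         # per-treatment networks, roles
Rscript analysis/05_recovery.R        # recovery vs planted correlation
```

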