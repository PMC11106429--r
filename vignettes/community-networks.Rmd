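---
title: "Methods: diversity and co-occurrence network analysis of OTU tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity and co-occurrence network analysis of OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

amonet implements the community-analysis chain that amplicon studies of
ammonia oxidizers (and microbial communities generally) run downstream of
OTU picking: rarefaction and alpha diversity, Bray–Curtis ordination with
ANOSIM, and Spearman-thresholded co-occurrence networks with topology
metrics and Zi–Pi node roles. This vignette documents the models, the
parameters that matter, the numerical conventions, and what the synthetic
validation does and does not demonstrate.

## The input and its normalization

Everything starts from an OTU-by-sample table of integer read counts plus a
sample-to-group mapping. Sequencing depth is a nuisance covariate: samples
are rarefied — subsampled without replacement — to a common depth before any
comparison, conventionally the lowest per-sample total (in amoA surveys
depths differ several-fold between samples). `rarefy()` performs a single
seeded draw by default, matching the usual one-shot subsampling; averaging
over repeated draws is available via `times`, trading a small bias
reduction for non-integer expectations that are rounded back to counts.
All-zero OTU rows created by rarefaction are retained: silently changing
the table's dimensions would complicate downstream bookkeeping, so
filtering is left as an explicit caller decision.

## Alpha diversity

`shannon()` computes \(H = -\sum_i p_i \log p_i\) over nonzero proportions,
in natural-log units. Literature is split between log bases; nats are the
default and `base` exposes 2 and 10. `chao1()` uses the classic
nonparametric richness estimator
\(S_{\mathrm{obs}} + F_1^2 / (2 F_2)\) from singleton and doubleton counts,
switching to the bias-corrected form
\(S_{\mathrm{obs}} + F_1 (F_1 - 1) / (2 (F_2 + 1))\) when \(F_2 = 0\),
where the classic form is undefined. Both error on all-zero vectors rather
than returning a conventional value.

## Beta diversity and group testing

`bray_curtis()` is the normalized absolute-difference dissimilarity
\(d_{xy} = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)\), computed on rarefied
counts (via `vegan::vegdist`). `pcoa()` is classical metric scaling: Gower
double-centering of the squared dissimilarities and eigendecomposition,
coordinates scaled by the square root of the eigenvalues. Bray–Curtis is
semimetric, so negative eigenvalues are expected; they are reported
untouched and excluded from coordinates, with no correction by default
(Lingoes and Cailliez are available via `correction` for users who need a
fully Euclidean representation). Proportions explained are fractions of the
positive-eigenvalue variance.

`anosim()` tests whether between-group dissimilarities exceed within-group
dissimilarities using the rank-based statistic
\(R = (\bar r_B - \bar r_W) / (M/4)\) with \(M = n(n-1)/2\), average ranks
for ties (ties are common in sparse tables), and a seeded uniform
permutation of group labels. The p-value uses the inclusive add-one
estimator \((1 + \#\{R^* \ge R\}) / (1 + N_{\mathrm{perm}})\), default 999
permutations, so the smallest attainable p is \(1/(N_{\mathrm{perm}}+1)\).

## Co-occurrence networks

The network stage is the computational core. `spearman_matrix()` ranks each
OTU's counts across samples (average ties) and correlates the ranks;
two-sided p-values come from the t approximation
\(t = \rho \sqrt{(n-2)/(1-\rho^2)}\) on \(n-2\) degrees of freedom, with
\(p = 0\) at \(|\rho| = 1\). Constant OTUs, whose rank correlation is
undefined, are dropped with a warning; a prevalence filter is available but
defaults to keeping all OTUs. `build_network()` retains an edge when the
correlation is strong and significant — strictly \(|\rho| > 0.7\) and
strictly \(p < 0.01\) by default, so a coefficient of exactly 0.7 is
rejected. Both signs qualify, because strong negative co-occurrence
(exclusion) is as informative as positive; `positive_only` reproduces a
sign-restricted reading. No multiple-testing correction is applied by
default, matching the raw-threshold convention of co-occurrence studies;
p-matrices are returned so users can apply `p.adjust` before thresholding
if they prefer. Nodes are the OTUs incident to at least one retained edge.

`topology()` reports the standard descriptor set: node and edge counts,
average degree \(2E/N\), edge density \(2E/(N(N-1))\), linkage density
("complexity") \(E/N\), average shortest-path length over connected pairs
only (thresholded correlation graphs are routinely multi-component, and
per-pair averaging is the convention of the graph tools this field uses;
largest-component averaging would silently change the population of pairs),
and the mean local clustering coefficient with degree-<2 nodes contributing
zero. The three degree identities hold exactly by construction, which makes
them a useful audit on any published node/edge/metric triple. An empty
network reports `NA` metrics rather than zeros: a path length of 0 is a
claim, an `NA` is an absence.

`detect_modules()` maximizes Newman modularity by the Louvain algorithm at
resolution 1.0, seeded; module labels are canonicalized by decreasing
module size so output is stable across runs. `zi_pi()` computes the
Guimerà–Amaral role coordinates: the within-module degree z-score
\(Z_i = (k_{i,s} - \bar k_s)/\sigma_s\) over the nodes of i's own module s,
and the participation coefficient \(P_i = 1 - \sum_s (k_{is}/k_i)^2\).
When a module's within-degree standard deviation is zero, \(Z_i = 0\):
identical nodes are by definition not hubs. Roles follow the 2.5 / 0.62
grid (peripheral, connector, module hub, network hub); values exactly on a
threshold fall in the lower category, reading the defining inequalities as
strict.

## The synthetic-data generator

`generate_dataset()` draws count tables by a Gaussian copula over
negative-binomial marginals. A latent multivariate normal per sample has
block-diagonal correlation — one block per planted module at its
`intra_correlation`, zero elsewhere — and is mapped through
\(\Phi\) to uniforms, then through each OTU's NB quantile function. The
copula was chosen because every downstream statistic here is rank-based:
only the rank structure of the latent field matters, and the copula
transfers it into counts exactly, up to discretization. The NB marginal
(variance \(\mu + \phi\mu^2\), default \(\phi = 0.5\)) matches the
overdispersion convention for amplicon counts. Baseline mean abundances are
log-normal with \(\sigma = 1.5\), giving the long-tailed rank-abundance
profile of real surveys; means are scaled to a per-sample depth drawn
around `depth_mean` (default 50,000 reads, CV 0.1 — the order of magnitude
of rarefied amoA libraries). Group structure multiplies the means of each
group's designated OTUs by \(e^{\mathrm{group\_effect}}\); designated
blocks are disjoint across groups and taken deterministically from the tail
of the OTU list, away from the planted modules at its head, so that
a nonzero `group_effect` separates groups by construction and mean shifts
do not contaminate the correlation ground truth. One global seed drives
reproducible per-stage sub-streams.

The default design is three groups of 10 replicate samples. Real amoA field
studies often have 3 plots per treatment; 3 samples cannot support Spearman
thresholding at P < 0.01 (the smallest two-sided p at n = 3 exceeds 0.01
for any non-degenerate ranking), so per-treatment networks need pooled
samples or deeper replication, and the generator defaults to a sample size
at which the network stage is statistically meaningful.
`spearman_matrix()` refuses n < 4 and warns below n = 10.

What the generator does *not* emulate: compositional closure effects
(counts are drawn per-OTU, not as a fixed-sum multinomial), taxonomic
structure, chimeras or OTU-clustering artifacts, and environmental
gradients. Passing the recovery suite therefore shows the inference chain
is correct and well-calibrated on overdispersed correlated counts — not
that ρ-thresholded networks recover ecological interactions in real
communities, where compositionality alone can induce spurious correlation.

## Validation choices and problem sizes

The test and acceptance suites run the chain at sizes chosen to keep the
Monte-Carlo standard errors comfortably inside the asserted bands: the
Spearman implementation is checked against the brute-force tie-free rank
formula on 1,000 random 8-sample pairs (agreement to 1e-12); PCoA must
reconstruct Euclidean-embeddable distances to 1e-8; ANOSIM's type-I error
is estimated from 200 null datasets at 999 permutations (band 0.05 ± 0.03);
planted-structure recovery uses 4 modules of 10 OTUs among 100 at n = 50
samples and depth 50,000, where latent correlation 0.9 maps to Spearman
≈ 0.89 and recovery should be essentially perfect; the monotonicity ladder
{0.0, 0.3, 0.6, 0.9} holds the seed fixed so it isolates the effect of the
planted correlation.

## Known limitations

- Spearman co-occurrence ignores compositionality; SparCC-style inference
  is out of scope by design.
- Average path length over connected pairs is not comparable across
  networks with very different component structure.
- Chao1 assumes singletons are real; denoised pipelines that remove
  singletons make it equal observed richness.
- The t approximation for Spearman p-values is asymptotic; at n < 10 the
  package warns, and `spearman_matrix(..., exact = TRUE)` switches to the
  exact permutation distribution (tie-free pairs only — ties fall back to
  the approximation).
- Rarefaction discards data; a single draw adds sampling noise that the
  `times` option can average away at the cost of non-integer counts.
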