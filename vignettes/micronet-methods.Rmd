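---
title: "Methods: compositional networks, keystoneness and attack tolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional networks, keystoneness and attack tolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micronet)
```

micronet implements the statistical core of an anti-microbiota vaccination
analysis: given genus-level 16S count tables from groups of tick pools
(unfed ticks, ticks fed on mock-immunized hosts, and ticks fed on hosts
immunized against a keystone or a non-keystone bacterium), it infers
compositionally robust co-occurrence networks, scores keystoneness, measures
the network's tolerance to node removal, and quantifies the downstream
taxonomic and functional consequences of depleting a keystone taxon. This
vignette explains each model, its assumptions, and the design choices that
were genuinely open.

## The compositional correlation model (SparCC)

Sequencing counts are compositions: only relative abundances are observed,
and naive correlations between relative abundances are distorted by the
unit-sum constraint. The basis-correlation estimator works from pairwise
log-ratio variances,

$$t_{ij} = \mathrm{Var}\,\log(x_i / x_j),$$

which are invariant to per-sample scaling. Writing
$t_{ij} = \omega_i + \omega_j - 2\rho_{ij}\sqrt{\omega_i\omega_j}$
in terms of basis (absolute-abundance) variances $\omega$ and correlations
$\rho$, and assuming the network is sparse (most $\rho_{ij} \approx 0$),
row sums of $t$ give a linear system for $\omega$:
$((D-2)I + J)\,\omega = t\,\mathbf{1}$ for $D$ taxa. Correlations follow as
$\rho_{ij} = (\omega_i + \omega_j - t_{ij}) / (2\sqrt{\omega_i\omega_j})$,
clamped to $[-1, 1]$.

Implementation choices:

* **Dirichlet resampling.** Each of `n_inference_iter` (default 20)
  iterations draws per-sample fractions from `Dirichlet(counts + 1)`,
  propagating count uncertainty; iterations are aggregated element-wise by
  the median. A deterministic `(counts + 0.5)/colsum` route is provided for
  exact oracle checks.
* **Strong-pair exclusion.** The sparsity assumption is protected by up to
  `n_exclusion_iter` (default 10) rounds per iteration that remove the
  single most strongly correlated pair with `|rho|` above
  `exclusion_threshold` (default 0.1) from the linear system. Ties are
  broken by the lexicographically smallest taxon pair so runs are
  deterministic. Exclusion stops before any taxon would keep fewer than
  three informative partners, which would make the solve singular.
* **Negative basis variances.** The linear solve can return non-positive
  $\omega$ on noisy, near-null tables; these are clamped to the smallest
  positive estimate with a single summary warning per fit. This keeps
  $\rho$ defined for all taxa instead of silently dropping them.
* **Edge significance.** Permutation pseudo-p-values shuffle each taxon's
  counts independently across samples and re-run the full estimator;
  $p = (1 + \#\{|\rho_{perm}| \ge |\rho_{obs}|\})/(1 + n_{perm})$, so the
  smallest attainable value is $1/(n_{perm}+1)$. Edges require
  `|rho| >= r_min` (default 0.3) and Benjamini-Hochberg adjusted
  `p <= alpha` (default 0.05) across all pairs. Because permutation
  p-values are granular, BH at conventional `alpha` needs permutation
  counts of several hundred before any pair can pass on mid-sized tables;
  at demonstration scale the examples and tests use the
  correlation-threshold-only network (`alpha = 1`), and the thresholds are
  exposed because published edge counts cannot be reproduced without
  knowing the original cutoffs.

## Keystoneness and topology

All node-level scores operate on the absolute edge weights of the signed
network. Eigenvector centrality is computed by power iteration (tolerance
`1e-10`) on the `|weight|` adjacency with a positive diagonal shift — the
shift leaves eigenvectors unchanged but gives strict spectral dominance on
bipartite graphs, where unshifted iteration oscillates — and is
max-normalised. Kleinberg hub scores coincide with eigenvector centrality
on undirected graphs and serve as an internal consistency check.

A taxon is flagged keystone when all three hold:

1. centrality at or above the 0.9 quantile of node centralities,
2. ubiquity (fraction of samples with a nonzero count) at least 0.8,
3. mean relative abundance at or above the 0.75 quantile, jointly with (1).

The quantile and ubiquity defaults operationalise "high" centrality /
abundance and "ubiquitous"; they are deliberately exposed because any such
cut is a convention, not an estimate.

The topology report (nodes, edges, signed-edge percentages, diameter and
average path length on the largest component, average and weighted degree,
modularity and module count from greedy modularity maximisation on absolute
weights, average local clustering) mirrors the summary tables conventional
in co-occurrence studies. Published tables of this kind sometimes print
"modularity" values above 1, which standard Newman-Girvan modularity
cannot reach; micronet reports standard modularity in $[-0.5, 1]$ and
makes no attempt to reproduce such values.

## Attack tolerance

Connectivity loss after removing a node set $R$ is

$$CL = 1 - \frac{\text{reachable pairs after removing } R}
              {\text{reachable pairs of the intact graph}},$$

the convention of the network-robustness tool family used with these
analyses. Normalising by the intact graph's own reachable pairs (rather
than by $N(N-1)/2$) keeps $CL_0 = 0$ even when isolated nodes are retained.
Note one consequence: removing any single node of a complete graph $K_5$
already costs $1 - \binom{4}{2}/\binom{5}{2} = 0.4$ of the originally
reachable pairs, even though the remainder stays connected — $CL$ tracks
lost pairs, not disconnection per se.

Random attacks average the loss curve over `n_iterations` (default 100)
uniformly random removal orders; directed attacks remove nodes in
decreasing betweenness centrality computed once on the intact unweighted
graph (ties by node ID), matching the "highest first" prescription; a
`recompute` option re-ranks after every removal. The summary statistic is
the smallest removal fraction whose step-function loss reaches 0.90, with
no interpolation.

## Diversity and group tests

Alpha diversity uses natural-log Shannon entropy over nonzero counts,
Pielou evenness $J = H/\ln S_{obs}$ with observed richness (undefined and
flagged for single-taxon samples), and Faith phylogenetic diversity
including the root connection (unrooted trees are midpoint-rooted with a
warning). Tables are rarefied to even depth by a single seeded draw
without replacement (default depth: the minimum sample sum); averaging
over draws is deliberately not done, matching common pipeline behaviour,
and the seed is recorded. Beta diversity is Bray-Curtis; PERMANOVA uses
free label permutation (default 999) with the `(1 + \text{more extreme})/
(1 + n_{perm})` convention. Bray-Curtis, PERMANOVA, rarefaction and Faith
PD are delegated to vegan and picante behind the package's interfaces.
Note that with very small groups the permutation space is tiny (4+4
samples admit only 70 distinct splits), so attainable p-values are floored
well above $1/(n_{perm}+1)$.

## Differential abundance

The two-group test is a negative-binomial Wald test on median-of-ratios
normalised counts: per-feature dispersion by the method of moments,
$\alpha = \max((s^2 - \mu)/\mu^2,\ 10^{-8})$ averaged over the two groups;
$LFC = \log_2((\bar{x}_2 + 0.5)/(\bar{x}_1 + 0.5))$ with the 0.5 offset
guarding zeros; the standard error comes from the NB variance of each
group mean via the delta method; BH adjustment across features. This is a
deliberate simplification of the shrinkage-based estimators used by
dedicated RNA-seq packages — no dispersion sharing across features, no
outlier filtering — because the planted-signal recovery the package is
validated on exercises the NB Wald machinery itself, not a particular
shrinkage scheme. Zero-heavy tables fall back to positive-count geometric
means for the size-factor reference. The clr transform
(`log(x + 0.5)` centered per sample) is provided for reporting, and
`volcano_table()` applies the conventional `|LFC| >= 1`, adjusted
`p < 0.05` flagging. Pathway-level significance can equally be assessed
with the Kruskal-Wallis wrapper when a rank test is preferred; both routes
are exposed.

## Covariate (antibody) correlation

Taxon-covariate association propagates compositional uncertainty by
Dirichlet Monte-Carlo: each of `n_instances` (default 128, the convention
of ALDEx2-style analyses) instances draws per-sample compositions from
`Dirichlet(counts + 0.5)`, clr-transforms them, and Spearman-correlates
each taxon with the covariate; p-values are BH-adjusted within each
instance before averaging, and all reported quantities are expectations
over instances. Spearman p-values use the t approximation, adequate at the
sample sizes involved.

## Functional prediction and qPCR

Metagenome prediction implements only the deterministic copy-number step:
taxon abundances divided by 16S copy number (default 1), multiplied
through a taxon-by-gene copy-number table; pathway abundance aggregates
member genes by the mean (a sum option exists; pathway-minimisation
algorithms are out of scope). Phylogenetic placement and hidden-state
prediction belong to upstream tools; users of real placement output can
pass an exclusion list (e.g. from an NSTI cutoff) to drop unreliable taxa.
qPCR fold changes use $2^{-\Delta\Delta C_t}$ with $\Delta C_t$ against a
housekeeping gene and the control-group mean as baseline, so control fold
changes have geometric mean 1; a per-group baseline was chosen because a
per-sample pairing is not generally available.

## The synthetic-data generator

`simulate_microbiome()` produces the full study design: four groups
(default 7 pooled samples each), a planted hub (keystone) taxon with
`n_satellites = 8` satellite taxa loading on the hub's latent factor at
`hub_satellite_rho = 0.8` (so satellite pairs correlate at $\rho^2$),
log-normal latent abundances closed to fractions and sampled multinomially
at `depth = 20000` reads, hub depletion by `depletion_factor` (default
0.25) in the keystone-vaccinated group, antibody OD kinetics whose
terminal value decreases monotonically with the realized hub fraction (so
noise-free OD and hub abundance have Spearman correlation exactly -1 in
the coupled groups), a coalescent phylogeny, hub-exclusive marker genes
(`atoB`, `eutD`) mapped to a single marker pathway, and Ct values whose
$2^{-\Delta\Delta C_t}$ tracks the realized hub fraction. One master seed
drives deterministic child seeds for every sub-generator.

The between-sample dispersion default `log_sd = 0.4` models *pool-level*
variability: samples represent 5-tick pools, and averaging across the
ticks of a pool damps individual-tick log-scale variation (roughly 0.9-1.0
for genus-level microbiome data) by about $\sqrt{5}$. Simulating pools at
tick-level dispersion would overstate between-sample noise to the point
where a 4-fold depletion is not reliably estimable from 10 pools per group
— no estimator can beat the $\sigma\sqrt{2/n}$ floor on the log-ratio of
group means — which is inconsistent with the designed recoverability of
the planted effect at study-like sizes.

What the generator does *not* emulate: taxonomic misassignment and
denoising artifacts, over-dispersion beyond log-normal (no zero
inflation), phylogenetic signal in abundances (the tree is independent of
the count model), and ecological interactions beyond the single
hub-satellite factor. Passing the recovery suites therefore demonstrates
that the estimators recover the structure they model, not that real tick
microbiome data meet these assumptions.

## Problem sizes and determinism

The test and demonstration scenarios use 30 taxa, 28-40 samples, depth
20000, 20 SparCC iterations, 100-200 permutations and 50-seed recovery
panels; these sizes were chosen so the planted effects sit comfortably
above their estimation floors while full runs stay interactive. Every
stochastic routine takes an explicit seed, derives child seeds
deterministically, and restores the caller's RNG state, so pipeline reruns
are byte-identical given the same configuration.

## Known limitations

* Permutation pseudo-p-values are granular; BH-corrected edge calling
  needs permutation counts in the hundreds to have any power on tables
  with many pairs.
* The NB Wald test is mildly anticonservative at very small group sizes
  (raw type-I around 0.05-0.08 at n = 10 per group in the null
  calibration); BH-adjusted calls remain strongly conservative.
* The basis-correlation sparsity approximation degrades when many strong
  correlations coexist; the exclusion heuristic mitigates but does not
  remove this.
* Published edge counts, modularity values and attack-removal fractions
  from sequencing studies depend on unstated thresholds and upstream
  processing; micronet reproduces their *arithmetic* (percentages, degree,
  centrality ratios) and their *qualitative* structure (directed attacks
  dominate random ones on hub-dominated networks), not the original
  numbers themselves.
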