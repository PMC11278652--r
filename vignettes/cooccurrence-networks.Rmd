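---
title: "Co-occurrence networks of riverine bacteria and archaea: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence networks of riverine bacteria and archaea: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverweb)
```

## The problem

Planktonic bacteria and archaea in a large river do not associate at
random: OTUs that respond to the same environmental drivers, exchange
metabolites, or share a niche co-vary in abundance across sampling sites.
`riverweb` implements the standard correlation-network workflow used to
quantify that non-randomness along a river continuum sampled at many sites
in two seasons: build a thresholded Spearman co-occurrence network per data
slice, compare it against Erdős–Rényi null ensembles, summarize intra- and
inter-phylum association with an observed-versus-random incidence ratio,
flag keystone taxa, and relate network structure to geography and water
chemistry.

## Network construction

Within a scope (spring samples, autumn samples, or all samples):

1. **Prevalence filter.** Only OTUs present (abundance > 0) in at least
   30% of the scope's samples enter the correlation step; the boundary is
   inclusive (3 of 10 samples passes). Rare OTUs produce unstable rank
   correlations dominated by shared zeros, which this filter removes.
2. **Spearman correlations.** Every OTU pair gets a tie-corrected Spearman
   rho (Pearson correlation of average ranks). Two-sided p-values use the
   t approximation with n − 2 degrees of freedom, standard at the n ≈
   59–118 samples this design produces; an exact permutation p would shift
   q-values only marginally. Constant OTUs are excluded with a logged
   count. Fewer than 5 samples is an error, since the approximation is
   meaningless there.
3. **Multiple testing.** Benjamini–Hochberg across *all* tested pairs of
   the scope (not per domain).
4. **Edge rule.** rho > 0.6 **and** q < 0.01, both strict, positive
   correlations only. The positive-only rule is deliberate: the network is
   a co-existence network, and the thresholds are exposed in
   `run_config()` together with a `use_absolute` switch for sensitivity
   analyses. OTUs left without any edge are dropped — reported node counts
   describe the drawn network.
5. **Modules.** Seeded Louvain on the unweighted graph; module ids are
   relabelled 1, 2, … by descending size, and the modularity value is
   stored on the graph. Louvain's tie-breaking is randomized, so the seed
   is part of the configuration.

Because bacteria and archaea are typically profiled with separate primer
sets, their read pools are not directly comparable.
`normalize_by_domain()` rescales each domain to sum 1 per sample before
merging, so cross-domain correlations compare within-domain relative
profiles; it is off by default because input tables may already be merged
consistently, and rank correlations are unaffected for within-domain
pairs either way.

## Null models and the small-world coefficient

For a network with N nodes and M edges we sample uniform simple graphs
with exactly those counts (G(n, m)) and record per replicate the mean
local clustering coefficient CC (nodes of degree < 2 contribute 0), the
average shortest-path length APL over connected pairs, and Louvain
modularity MD. The small-world coefficient is

σ = (CC / CCr) / (APL / APLr),

with the r-subscripted quantities the ensemble means. σ ≫ 1 indicates
clustering far above and path lengths near those of an equal-size random
graph. Two numerical choices are worth stating because disconnected
graphs make naive definitions undefined: APL averages over connected
pairs only (keeping it finite for both real and random graphs), and CC is
the mean *local* clustering coefficient, whose ensemble mean converges to
the edge density m/C(n, 2) — the estimator whose values the random-graph
columns of published comparison tables reproduce. Global transitivity is
computed separately among the topology features. With zero edges CC is 0
and APL is reported missing, never 0.

Degree-distribution model comparison fits P(k) by nonlinear least squares
to a·k^(−γ) and to a Gaussian A·exp(−(k − μ)²/(2s²)), both on raw
probabilities so the two adjusted R² values (1 − (1 − R²)(n − 1)/(n − p −
1), n = number of distinct degrees, p = parameter count) are directly
comparable. Fitting on log-transformed residuals would weight the tail
differently for the two models and break that comparability, which is why
raw probabilities are the default. Starting values come from log–log OLS
(power law) and histogram moments (Gaussian), with a small restart grid;
a non-convergent fit is flagged rather than silently dropped. A random
G(n, m) graph's binomial-like degree histogram favors the Gaussian; a
preferential-attachment graph favors the power law — the direction the
workflow uses to call a network scale-free.

## O/R incidence and keystones

For each unordered phylum pair, the observed incidence O is the percent
of all edges joining that pair. The random incidence R is the expected
percent if the same number of edges were placed uniformly at random among
the N nodes, which reduces to the closed form n₁·n₂/C(N, 2) between
distinct phyla and C(n₁, 2)/C(N, 2) within one — no Monte-Carlo is
needed, and both O and R sum to exactly 100% over all pairs. The O/R
ratio is computed on unrounded values (printed tables that show 0.93 and
0.08 alongside a ratio of 11.94 demonstrate that rounding happens only at
display). Reports conventionally keep rows with O > 0.5% and O/R > 1,
both strict.

Keystone taxa are nodes with degree > 100 and unnormalized betweenness
centrality < 5000 (both strict): highly connected OTUs that are not mere
bridges. Betweenness is kept unnormalized precisely so this published
cutoff applies directly; the cutoffs are configuration values meaningful
only for networks of comparable scale (hundreds of nodes, tens of
thousands of edges). An empty keystone set is a valid outcome and still
produces a full report. Because it is ambiguous whether a "percent of
total abundance" for keystones should be taken over the keystone set or
the whole network, the report provides both denominators.

## Topological features

The canonical 12-feature set (`TOPOLOGY_FEATURES`): node count, edge
count, graph density, transitivity, average clustering coefficient,
average degree, Freeman degree centralization Σ(k_max − k_i)/((n−1)(n−2)),
average nearest-neighbor degree, average path length, average
(unnormalized) betweenness, Louvain modularity, and degree assortativity.
The graph is treated as unweighted throughout. Features undefined on a
degenerate graph (assortativity with zero degree variance, path length of
an edgeless graph, centralization below 3 nodes) are reported missing,
never coerced to 0.

Per-sample subnetworks are the induced subgraphs on the network nodes
with abundance > 0 in that sample — no minimum-abundance floor, and edges
survive only if both endpoints are present. One feature row per sample,
annotated with season/landform/region, feeds the group comparisons:
two-sided Wilcoxon rank-sum (normal approximation, tie-corrected) for two
groups, one-way ANOVA for more, with any group under 3 samples flagging
the comparison rather than computing it.

## Spatial and environmental analysis

**Distances.** Geographic distance is haversine on a sphere of radius
6371.0088 km. Any geodetic model differing by a monotone transform gives
identical Spearman-based Mantel statistics, so this choice is inert for
the tests built on it. Community and feature dissimilarity is Bray–Curtis;
topology-feature matrices contain negative-valued features
(assortativity), so they are min–max scaled per feature to [0, 1] first,
with constant features dropped.

**Mantel.** The statistic is the Spearman correlation of the two distance
matrices' upper triangles; the null comes from simultaneous row/column
permutation of one matrix, and the one-sided p is (#{r_perm ≥ r_obs} +
1)/(permutations + 1) — one-sided because distance-decay is a directional
hypothesis. The distance-decay fit itself is OLS of Bray–Curtis
*similarity* (1 − dissimilarity) on distance over all pairs; the slope
(per km) is descriptive, the Mantel test carries the inference.

**db-RDA.** Bray–Curtis dissimilarities are double-centered and
eigen-decomposed; axes with negative eigenvalues are dropped and the
retained coordinates are regressed on standardized environmental factors.
Axis percentages are constrained eigenvalues over the total retained
inertia. Per-factor tests are *marginal* (one constraint at a time):
R² with a permutation p, and the permutation-adjusted
R²_adj = 1 − (1 − R²)/(1 − mean(R²_perm)), which corrects the upward bias
of raw R² under constrained ordination. Marginal rather than sequential
tests were chosen because they do not depend on factor order. Missing
environmental values are handled pairwise-complete for the Spearman
heatmap and listwise for the ordination. A constraint matrix with
condition number above 1e8 is refused with the offending factors named.

## The synthetic generator

`simulate_community()` produces data with exactly the statistical
structure the pipeline assumes, so every stage is testable without
sequencing data. Defaults emulate the study design scale: 59 sites × 2
seasons (118 samples), 600 OTUs, 8 planted modules of 45 OTUs at
intra-module latent correlation 0.9, zero-inflation 0.2, spatial decay
length 1000 km over a 6000 km river.

* **Latent-factor log-normal model.** Each module has one latent Gaussian
  factor per sample; member log-abundances load on it with loading
  √ρ, giving any two members latent correlation ρ. Spearman's rho is
  invariant to the exponential transform, so target correlations are
  predictable — the reason this model was chosen over a Dirichlet.
* **Spatial structure.** Factors are drawn with covariance
  exp(−d/decay_length) in along-river distance, independently per season;
  this is what gives Mantel tests a distance-decay signal to find.
* **Environment.** Each factor is baseline + autumn offset + along-river
  gradient + noise; the default water-temperature contrast is +10.6 °C in
  autumn, with ammonium and the metals Ca/Fe/Al/Ni elevated in spring,
  mirroring the seasonal chemistry of a monsoonal river.
* **Zero inflation** is Bernoulli masking to exact zeros followed by row
  renormalization, exercising the prevalence filter and the per-sample
  subnetwork rule.

What the generator does *not* emulate: sequencing depth and rarefaction
(it works directly in relative abundance), compositional coupling beyond
closure, taxonomic correlation between module membership and phylum, and
chimeras or any sequence-level artifact. Passing recovery tests therefore
demonstrate the pipeline's correctness on data satisfying its own
assumptions, not robustness to amplicon-processing artifacts.

## Problem sizes and reproducibility

The test suite runs the generator at 100–200 OTUs and 16–30 sites, ER
ensembles at 100 replicates, and permutation tests at 99–399
permutations; these sizes give stable pass/fail behavior for the
properties checked (module recovery ARI > 0.7, FDR control, Mantel
type-I calibration) while keeping the suite quick. The acceptance script
recomputes the printed small-world coefficients exactly and the ER
clustering means with 100 replicates at the real network sizes (838–1071
nodes). All randomized steps (generator, Louvain, G(n, m), permutations)
take explicit integer seeds and are bit-reproducible under them.

## Known limitations

* Rank correlations on closed (relative) data carry compositional bias;
  SparCC/SPIEC-EASI-style compositionality-aware inference is out of
  scope by design.
* The Erdős–Rényi null preserves only N and M, not the degree sequence;
  no configuration-model null is provided.
* Along-river (hydrologic) distance is not computed; geographic distance
  is straight-line geodetic.
* Keystone cutoffs are absolute, not scale-adjusted; apply them only to
  networks of comparable size.
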