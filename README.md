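# riverweb

Co-occurrence network analysis of planktonic bacteria and archaea along a
river continuum.

Microbial ecologists working with 16S amplicon surveys of large rivers ask
whether prokaryotic taxa co-exist non-randomly: do OTUs associate within
their own domain and phylum more than chance predicts, which taxa hold the
network together, and how do season, landform and water chemistry reshape
those associations? `riverweb` packages the full workflow for answering
these questions from an OTU relative-abundance table, a taxonomy map and
sample metadata — plus a synthetic community generator so the entire
pipeline is testable without sequencing data.

## The method

* **Network construction.** Within a scope (spring / autumn / both), OTUs
  present in ≥ 30% of samples are correlated pairwise with tie-corrected
  Spearman's ρ; edges require ρ > 0.6 and Benjamini–Hochberg q < 0.01
  (strict, positive correlations only). Modules come from seeded Louvain.
* **Null comparison.** 1000 (configurable) Erdős–Rényi G(n, m) graphs at
  the real network's size give CCr, APLr, MDr; the small-world coefficient
  is σ = (CC/CCr)/(APL/APLr). Degree distributions are fit to a·k^(−γ)
  and to a Gaussian, compared by adjusted R².
* **O/R incidence.** For each phylum pair, the observed share of edges O%
  against the share R% expected under uniformly random edge placement —
  R = n₁n₂/C(N,2) between phyla, C(n₁,2)/C(N,2) within one. O/R > 1 means
  more co-existence than chance.
* **Keystones.** Nodes with degree > 100 and unnormalized betweenness
  < 5000 (both strict, configurable).
* **Topology.** The 12 network-level features (density, transitivity,
  clustering, degree statistics, centralization, path length, betweenness,
  modularity, assortativity) on whole networks and on per-sample
  presence-induced subnetworks, with Wilcoxon / ANOVA group comparisons.
* **Space and environment.** Haversine geodetic distances, Bray–Curtis
  dissimilarities, Mantel distance-decay tests (Spearman statistic, 999
  permutations), Spearman heatmaps of environment × module/feature
  associations, and distance-based redundancy analysis (db-RDA) with
  marginal permutation tests per environmental factor.

See `vignettes/cooccurrence-networks.Rmd` for the full methods account
and design rationale.

## Worked example

```r
library(riverweb)

spec <- community_spec(n_otus = 200, n_sites = 40,
                       module_spec = data.frame(size = rep(30, 4), rho = 0.9),
                       zero_inflation = 0.1, seed = 42)
ds <- simulate_community(spec)

net <- build_cooccurrence_network(ds$table, ds$taxonomy, ds$metadata,
                                  scope = "both")
topo  <- compute_topology(net)
nulls <- sample_er_ensemble(igraph::vcount(net), igraph::ecount(net),
                            n_graphs = 100, seed = 1)
small_world_sigma(topo$avg_clustering, nulls$CCr,
                  topo$avg_path_length, nulls$APLr)

inc <- filter_incidence_report(phylum_pair_incidence(net))

sp <- ds$metadata[ds$metadata$season == "spring", ]
dd <- distance_decay_fit(geodetic_distance_matrix(sp),
                         bray_curtis_matrix(ds$table[sp$sample_id, ]),
                         n_permutations = 999, seed = 1)
```

Output:

```
nodes: 110  edges: 679  modules: 4  modularity: 0.724
CC: 0.728  CCr: 0.113  APL: 1.607  APLr: 2.106  sigma: 8.451
        phylum_1       phylum_2 n1 n2 edge_count     O     R ratio
1 Proteobacteria Proteobacteria 32 32         64 9.426 8.274  1.14
2  Acidobacteria Actinobacteria  3 12          5 0.736 0.601  1.23
distance-decay slope: -3.71e-05 per km; Mantel r: 0.2703  p: 0.001
```

Reading it: the pipeline recovered the 4 planted modules among the 110
OTUs that survived thresholding; clustering is ~6× the random expectation
at shorter-than-random paths, hence a strongly small-world σ of 8.45;
Proteobacteria–Proteobacteria edges are 1.14× their random share
(intradomain preference); and spring community similarity decays
significantly with distance (Mantel r = 0.27, p = 0.001), the
distance-decay signal the generator's spatial autocorrelation plants.

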