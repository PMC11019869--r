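# riveremf

Ecosystem multifunctionality (EMF) and microbial co-occurrence network
analysis for river ecosystems sampled along a latitudinal gradient.

River surveys that sample channel sediments, riparian rhizosphere soils and
riparian bulk soils across tens of sites typically measure many ecosystem
functions at once — nitrogen-cycling rates (nitrification, denitrification,
anammox), soil/sediment nutrient pools (TC, TOC, TN, NO₃⁻, NH₄⁺, TP), plant
biomass and water-quality proxies (DO, TDS, TOC, TN, NH₄⁺, NO₃⁻, TP,
chlorophyll-a) — together with shotgun-metagenomic taxon tables. This
package implements the statistical chain that turns those measurements into
latitudinal-gradient results, for ecologists who want the analysis scripted,
tested and reproducible rather than spread across ad-hoc R snippets.

## What it computes

**Multifunctionality.** Variables whose increase is undesirable (the water
nutrient-load variables) are multiplied by −1, then every function is
min–max standardized, `STD = (X − X_min)/(X_max − X_min)`, onto a common
0–1 scale. Three index families follow:

- `EMF_average` — the arithmetic mean of the standardized functions,
- `EMF_weighted` — the mean of per-category means, giving the four
  functional categories (nitrogen cycling, nutrient pools, plant
  productivity, water quality) equal weight,
- the multiple-threshold index — for every threshold *t* ∈ {5%, …, 95%}
  the number of functions reaching *t* of their maximum, later regressed
  on latitude to give a threshold–slope curve.

**Community.** Observed richness and Shannon diversity (nats), Bray–Curtis
dissimilarities, NMDS ordination and ANOSIM group tests (via vegan).

**Co-occurrence networks.** After removing taxa with summed relative
abundance < 0.01%, all pairwise Spearman correlations are tested, p-values
are Benjamini–Hochberg adjusted over the whole family, and edges with
|ρ| > 0.65 and q < 0.01 are retained. Per-sample subnetworks (the subgraph
induced by the taxa present in a sample) are scored with ten topological
metrics — node and edge number, mean degree, connectance, average path
length, diameter, edge connectivity, degree and betweenness centralization
(Freeman-normalized), global clustering coefficient — plus greedy
Newman–Girvan modularity. A network-complexity index is the first
principal axis of the z-scored metric table, with average path length and
diameter negated first (they measure sparsity).

**Gradient statistics.** OLS regressions of any index on latitude with
95% CIs, per-threshold slope curves, Mann–Whitney U contrasts between
low- and high-latitude site groups (split at the ~33° N Qinling–Huaihe
line by default), and Spearman correlation screens against environmental
drivers.

**Synthetic data.** `simulate_functions()` and `simulate_abundances()`
generate function tables and genus matrices with planted latitude effects,
Gaussian niche turnover and correlated taxon guilds, returning the ground
truth so every stage can be validated by parameter recovery.

## Worked example

```r
library(riveremf)

## 30 sites x 3 habitats, 18 functions declining with latitude
sim <- simulate_functions(simulation_config(seed = 1))
res <- emf(sim$table)
res
#> EMF indices for 90 samples, 18 functions
#>   EMF_average : mean 0.508, range 0.184-0.841
#>   EMF_weighted: mean 0.492, range 0.142-0.875
#>   Threshold grid: 5-95% (91 thresholds)

fit_latitude_regression(res$scores$emf_average, res$metadata)
#> Latitude regression (all habitats, n = 90):
#>   slope = -0.02614 per degree [-0.02707, -0.02521], R^2 = 0.973, p = 1.78e-70

## co-occurrence network with planted guilds (correlation 0.95)
ab <- simulate_abundances(simulation_config(n_sites = 40,
        habitats = "sediment", guild_correlation = 0.95, seed = 1))
net <- build_network(ab$abundance)
net
#> Co-occurrence network: 200 taxa, 272 edges (|rho| > 0.65, q < 0.01, 40 samples)
#>   positive edges: 271, negative edges: 1

complexity_index(sample_subnetwork(net, ab$abundance))
#> Network-complexity index (PC1 of 9 metrics): 56.3% of variance
```

The regression slope (−0.026 per degree) recovers the generator's implied
EMF slope (−0.0258 for this seed: the configured per-function decline of
0.01 raw units/degree divided by each function's realized range), and the
272 network edges recover all 270 within-guild pairs with essentially no
spurious cross-guild edges — the planted structure coming back out is what
the test suite asserts quantitatively.

`run_pipeline(list(out_dir = "run", seed = 1))` chains all stages and
writes every table as TSV plus a `manifest.json` with seeds, parameters
and output hashes; reruns are byte-identical.

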