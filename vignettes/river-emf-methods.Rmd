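---
title: "Methods: multifunctionality and network complexity along a latitudinal gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multifunctionality and network complexity along a latitudinal gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riveremf)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, and the numerical and design choices that a
user re-analysing their own river-survey data should know about.

## The multifunctionality model

A survey yields a samples-by-functions table: one row per (site, habitat)
pair, one column per measured ecosystem function. The default schema holds
18 functions in four categories — nitrogen cycling (potential
nitrification, denitrification, anammox rates), nutrient pools (soil or
sediment TC, TOC, TN, NO₃⁻, NH₄⁺, TP), plant productivity (biomass) and
water quality (DO plus TDS, TOC, TN, NH₄⁺, NO₃⁻, TP, chlorophyll-a of the
adjacent water column).

Two pre-processing steps put all functions on a comparable footing:

1. **Directional adjustment** (`apply_direction()`): functions whose raw
   increase degrades the ecosystem — the seven water nutrient-load and
   chlorophyll variables — are multiplied by −1, so larger always means
   better functioning. The schema's direction flags are reset afterwards,
   making the operation idempotent; this matters because pipelines often
   re-enter intermediate tables.
2. **Min–max standardization** (`standardize_functions()`):
   `STD = (X − X_min)/(X_max − X_min)` with the extrema taken per function
   across *all* samples. Consequences worth keeping in mind: each
   function's standardized values always span exactly [0, 1], so (a) a
   flipped function equals 1 − STD of its unflipped version, and (b) any
   slope estimated on the standardized scale is the raw-scale slope divided
   by the realized range — relevant when comparing recovered slopes to
   generating parameters (see below). A constant function carries no
   ranking information; it is set to 0.5 with a warning rather than
   dropped, which keeps sample scores comparable when one assay failed
   uniformly.

Three indices summarize a sample's multifunctionality:

- `emf_average()` — the mean of the standardized functions. Simple and
  dominant in the literature, but a category measured by many proxies
  (here, water quality with 8) implicitly gets more weight.
- `emf_weighted()` — the mean of per-category means, the standard remedy
  for that over-representation. With equally sized categories it reduces
  exactly to the average index (a property the tests exercise).
- `multi_threshold()` — for each threshold t on a percent grid (default
  5–95% in 1% steps), the count of functions at or above t% of that
  function's reference maximum. Two conventions are deliberate choices,
  both exposed as arguments: the reference maximum is the *observed*
  per-function maximum (`robust_max_k = 1`; a top-k mean is available for
  robustness against a single extreme sample), and "exceeds" is inclusive
  (`>=`), so ties at exactly the threshold count. Counts are non-increasing
  in t by construction.

Missing measurements propagate as `NA`: indices are computed over the
observed functions and `n_functions_used` is reported per sample, so users
can filter rather than having zeros silently imputed. Whether plant biomass
exists for every habitat or only once per site is left to the data — rows
simply carry `NA` where a function was not measured.

## Community analysis

Alpha diversity (observed richness; Shannon in nats — the natural-log
convention of the ecology literature), Bray–Curtis dissimilarity, NMDS and
ANOSIM are delegated to vegan, behind thin validated wrappers.
`nmds_ordination()` runs `metaMDS` with a fixed seed and a configurable
number of random restarts, disables the automatic transformations (inputs
are already a dissimilarity matrix), and returns the best solution with its
stress and a convergence flag rather than erroring when monoMDS's strict
convergence criteria are not met — on small, noisy community matrices they
frequently are not, while the solution is still usable; callers that
require convergence can test the flag. Ties in the monotone regression use
the primary treatment (tied dissimilarities may take equal fitted values).
`anosim_groups()` uses the standard statistic
R = (r̄ between − r̄ within)/(n(n−1)/4) and the permutation p-value
convention that counts the observed statistic in both numerator and
denominator.

## Co-occurrence networks

`build_network()` follows the common robust-correlation recipe:

1. remove taxa whose relative abundance summed over the input samples is
   below `min_rel_abund` (default 10⁻⁴, i.e. 0.01%) — correlations among
   near-absent taxa are rank artefacts;
2. Spearman correlations between all remaining taxon pairs (mid-ranks for
   ties), two-sided p-values from the t approximation;
3. Benjamini–Hochberg adjustment over the *entire* family of tested pairs
   in this construction (one network = one family: the reproducible
   choice);
4. retain edges with |ρ| > 0.65 and q < 0.01 (strict inequalities).

Retention uses |ρ|, keeping both co-presence and mutual-exclusion edges;
`positive_only = TRUE` restricts to co-presence, since "correlation above
a threshold" is read both ways in the literature. Edge counts are monotone
in both thresholds, and on independent noise the expected number of
retained edges is well below one — both properties are asserted in the
test suite.

Networks are built per sample group (in the pipeline: per latitude group,
mirroring designs that contrast low- vs high-latitude networks per
habitat), and `sample_subnetwork()` attributes topology to individual
samples via the subgraph induced by the taxa present (abundance > 0) in
that sample. Which network a subnetwork is induced from is explicit — the
function takes the network as an argument — because pooled-versus-global
constructions are both defensible.

### The ten topological metrics and their conventions

Node number, edge number, mean degree (2E/N), connectance (2E/(N(N−1))),
average path length, diameter, edge connectivity, degree centralization,
betweenness centralization and the global clustering coefficient
(transitivity: closed triplets over all triplets; the average-local variant
differs and is not the default). Centralizations are Freeman-normalized in
package code against the star-graph maximum — betweenness over unordered
pairs with endpoints excluded — rather than through igraph's
centralization helpers, so the convention is pinned down and the test
oracle (an independent BFS/path-enumeration implementation) is meaningful.

Ecological subnetworks are frequently disconnected or tiny, so degenerate
conventions are fixed rather than left to chance: average path length and
diameter are computed on the largest connected component (ties broken by
lowest vertex index; component count is reported alongside), edge
connectivity of a disconnected graph is 0, and graphs with fewer than two
nodes or no edges return 0 for path metrics, clustering, connectance and
centralizations. Modularity uses deterministic greedy agglomeration
(`cluster_fast_greedy`); exact modularity maximization is NP-hard and the
greedy optimum is reproducible run-to-run, which we value more than the
last decimal of Q.

### The complexity index

`complexity_index()` condenses the per-sample metric table to one axis:
average path length and diameter are negated (they measure sparsity),
every metric is z-scored, and the first principal component is returned
with its loadings and variance share. The axis is oriented so the loading
on edge number is non-negative — PCA axes have arbitrary sign, and "more
edges = more complex" fixes the direction interpretably. Constant metrics
(common: edge connectivity is 0 for most disconnected subnetworks) are
dropped with a message since they carry no variance.

## Gradient statistics

`fit_latitude_regression()` is OLS with t-based confidence intervals
(n − 2 df). The multiple-threshold result is summarized by
`threshold_slope_curve()`: an independent OLS per threshold, which is the
quantity such curves display; a mixed model with site-level random
intercepts would be the natural refinement for nested habitat data but is
deliberately out of scope — per-threshold OLS is stated openly rather than
imitating a mixed model loosely. Group contrasts use the Mann–Whitney U
test (exact p for untied groups of ≤ 8, normal approximation with tie and
continuity correction otherwise), matching the non-parametric practice for
skewed environmental data. `correlation_screen()` reuses the Spearman
machinery with BH adjustment over all pairs of one screen invocation.
All tests are two-sided; no significance stars are emitted.

## What the synthetic generator does and does not emulate

`simulation_config()` defaults describe a 30-site survey spanning
21.76–45.09° N with three habitats per site, split into low/high latitude
groups at 33° N (approximating the Qinling–Huaihe climatic boundary; an
option reproduces an 11/19 split design). Latitudes are stratified-uniform
— one draw per equal-width band — because balanced designs make the
recovery experiments sharper than clumped real-world site placement.

**Functions** are linear in latitude with Gaussian noise:
X = α + βL + habitat offset + ε. Defaults: α = 1, σ = 0.05 raw units, and
|β| = 0.01 per degree with the sign arranged so every function *declines*
with latitude after directional adjustment — a gradient of roughly 0.23
raw units over the 23.3° span, chosen so the planted signal is strong but
noise is visible. Habitat offsets default to 0 (habitat differences exist
in real surveys, but no generative model for them is claimed). Because
standardization divides by each function's realized range, the ground
truth reports the *implied* EMF-average slope, mean over functions of
β·direction/range — the quantity an OLS of EMF on latitude estimates —
rather than the raw β; the coverage experiments in the tests check the
95% CI against exactly this quantity.

**Abundances** follow a log-linear model: per-taxon log-normal baselines
(meanlog log 50, sdlog 0.8), a per-sample depth factor (sdlog 0.2),
Gaussian niche responses to latitude (random optima, common breadth
`turnover_scale` = 8°; ∞ disables the gradient) and a stochastic term of
scale 1.5 on the log scale. A guild — the planted structure networks
should recover — is a block of taxa (6 guilds × 10 taxa of 200 by
default) that share their niche optimum *and* a per-sample latent factor
with weight √r, giving within-guild latent correlation r
(`guild_correlation`, default 0.8, settable per latitude group to plant a
between-group complexity contrast). Counts are Poisson around the expected
abundance; a negative-binomial option adds overdispersion as a knob, not a
claim about real libraries. These magnitudes were fixed once, at design
time, so that planted structure is recoverable at the package's default
network thresholds.

Not emulated: compositionality of sequencing (counts are independent
Poisson given the latent layer, not a fixed-total multinomial), taxonomic
assignment error, habitat-specific community composition, spatial
autocorrelation beyond the latitude niche, and any mechanistic water
chemistry. Passing recovery tests therefore demonstrates that the
*statistical chain* is correct and calibrated — not that real river
metagenomes satisfy the generator's assumptions.

## Problem sizes and runtime choices

The test suite validates graph metrics against brute-force oracles
(BFS path enumeration, exhaustive min-cut over vertex bipartitions, direct
triplet counts) on 200 random graphs of ≤ 10 nodes, threshold counts
against naive double loops on 100 random 20 × 18 tables, null calibration
of ANOSIM and the latitude regression with 500 simulations each (199
permutations per ANOSIM call), network nulls over 100 iid datasets, slope
coverage over 200 replicates of a 60-sample survey, and the group-network
contrast over 30 seeds. These sizes give stable Monte-Carlo estimates of
the asserted rates while keeping a full test run in well under a minute of
simulation time per experiment.

## Known limitations

- Spearman co-occurrence on counts ignores compositional coupling; for
  strongly compositional data a dedicated method (SparCC-style) would be
  needed — intentionally out of scope.
- The threshold-curve analysis treats samples as independent; nested
  site/habitat structure is not modelled.
- Min–max standardization makes every index sensitive to the sampled
  extremes; comparisons across surveys standardized separately are not
  meaningful.
- Greedy modularity can merge small communities; reported Q is a lower
  bound on the optimum.
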