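---
title: "Network-based characterization of microbial communities with micronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based characterization of microbial communities with micronet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`micronet` builds genus-level microbial co-occurrence networks from 16S
rRNA count tables and compares them between host groups (for example
healthy controls against an inflammatory-bowel-disease cohort, or two
disease subtypes). This vignette explains the statistical models behind
each stage, the tunable parameters and their defaults, the synthetic-data
generator used throughout the tests, and the numerical and design choices
a user should be aware of.

## The pipeline at a glance

For each sample group the pipeline runs:

1. **Filtering** — drop shallow samples, then rare genera
   (`filter_counts()`).
2. **Zero replacement and closure** — Bayesian-multiplicative imputation
   of sampling zeros (`zero_replace()`), centered log-ratio transform for
   reporting (`clr_transform()`), and alpha diversity
   (`alpha_diversity()`).
3. **Association** — SparCC basis correlations (`sparcc()`), per-edge
   one-sample t-tests (`edge_significance()`), and local-false-discovery
   sparsification (`lfdr_adjust()`).
4. **Network analysis** — the sparsified graph (`build_network()`),
   fast-greedy clustering, global properties (`global_properties()`),
   centralities and hubs (`centralities()`, `hubs()`), and the two core
   microbiota definitions (`core_def1()`, `core_def2()`).
5. **Graphlets** — orbit counts up to four nodes (`count_orbits()`), the
   graphlet correlation matrix (`gcm()`), and the between-group Fisher
   z-comparison (`gcm_difference()`, `select_orbits()`, `map_genera()`).

Across groups, `property_difference_test()` runs a label-permutation test
for global network properties, `centrality_difference_test()` does the
same per genus, and `jaccard_test()` compares hub sets.
`run_comparison()` orchestrates everything and writes a TSV/GraphML/JSON
report bundle.

## Compositional preprocessing

Sequencing counts are compositional: only relative information is
meaningful, and naive correlations between relative abundances are
distorted by the unit-sum constraint. The pipeline therefore:

* **Filters** samples with fewer than 10,000 reads, then genera whose
  mean per-sample relative abundance is below 0.001% or that appear in
  fewer than 1% of samples. The abundance rule is implemented scale-free
  (mean of per-sample relative abundances); a literal variant (mean raw
  reads against the grand total) is available via
  `filter_config(abundance_rule = "literal")`. Filters run in one pass —
  samples first, then genera — and are idempotent.
* **Replaces zeros** with the Dirichlet-posterior expectation under a
  uniform prior over genera whose total strength is `sqrt(depth)` — a
  weak, depth-adaptive prior. A genus unobserved in a sample of depth
  `n` over `D` genera receives `sqrt(n) / (D * (n + sqrt(n)))` of the
  composition, and observed genera are rescaled multiplicatively so every
  column still sums to one. The prior-strength function is a parameter
  (`prior_strength`) for users who prefer a fixed-strength prior.
* **CLR-transforms** compositions for diagnostics and reporting. SparCC
  consumes the zero-replaced composition directly (it forms its own
  log-ratios); the CLR matrix is written alongside for inspection because
  the two conventions coexist in practice.

Alpha diversity uses Shannon entropy (natural logarithm, via `vegan`) and
the bias-corrected Chao1 estimator
`S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, which stays defined when there are
no doubletons; the classic `F1^2 / (2 F2)` form is available via the
`chao1` argument. Group comparisons use the two-sided Mann-Whitney test
(exact for small tie-free samples, tie-corrected normal approximation
otherwise).

## SparCC association inference

SparCC infers "basis" correlations from the log-ratio variation matrix
`t_ij = Var(log(x_i / x_j))` under a sparsity assumption. With row sums
`t_i` and `T = sum(t_i) / (2 (D - 1))`, the no-exclusion solution is
`omega_i = (t_i - T) / (D - 2)`, and correlations follow as
`rho_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j))`,
clipped to `[-1, 1]`. Because strong correlations violate the sparsity
assumption, the strongest not-yet-excluded pair with `|rho| > 0.1` is
iteratively removed from the linear system and the basis variances
re-solved, up to 10 times — the defaults of the original tool. Two
implementation notes:

* The original tool resamples counts from a Dirichlet posterior and
  aggregates many inner iterations; here zeros are already handled
  upstream, so a single deterministic pass on the zero-replaced
  composition is used. This makes the estimate reproducible and fast
  (the iteration core is compiled).
* On very small networks the automatic exclusion loop stops early rather
  than excluding a pair that would strand a genus or make the system
  singular; the user-facing `basis_variances()` still reports such
  degenerate exclusion sets as errors.

Edges are tested with `t = rho * sqrt((n - 2) / (1 - rho^2))` against a
t distribution with `n - 2` degrees of freedom — the sampling
distribution of a Pearson correlation, used here as an approximation for
SparCC estimates, as is common in this toolchain. Multiplicity is
handled by the local false discovery rate: z-scores
`atanh(rho) * sqrt(n - 3)` are modeled as a mixture, the empirical null
`N(mu0, sigma0^2)` and its proportion `pi0` are estimated by central
matching (a quadratic fit to the log kernel density around its mode), and
edges with `lfdr <= 0.05` are kept. The empirical null absorbs the mild
overdispersion that compositional estimation induces. With fewer than 50
pairs the density estimate is unreliable and the function demands the
Benjamini-Hochberg fallback (`method = "BH"`), which is also the
recommended setting for small ad-hoc analyses.

## Network properties

The network has one node per genus (isolated genera remain nodes and
count as components), signed correlations on the edges, `|rho|` as the
clustering/modularity weight, and `1 - |rho|` as the dissimilarity used
for shortest paths. Global properties follow the conventions of the
co-occurrence literature: component count, global transitivity of the
unweighted skeleton (the mean local coefficient is available via
`avg_local_clustering`), weighted fast-greedy modularity, positive-edge
percentage, edge density, natural connectivity
(`ln mean exp(lambda)` over adjacency eigenvalues of the unweighted
skeleton, computed with a log-sum-exp guard), and the *edge number* — the
product of edge density and component count, a combined complexity index.
On the largest connected component the pipeline adds the relative size,
mean edge dissimilarity, and the average shortest-path length in
dissimilarity units: the mean weighted path length divided by the mean
dissimilarity (the raw value is reported alongside). Averages run over
connected pairs only. The fast-greedy merge tree is cut at its
modularity maximum explicitly, because the library default can stop one
merge short on very small graphs; an edgeless graph is defined to have
`Q = 0` and one singleton cluster per node.

## Hubs, the Jaccard test, and the core microbiota

Degree is the unweighted edge count; betweenness and closeness use
dissimilarity path lengths. Closeness applies the reachable-fraction
correction `(r_i / (n - 1)) * (r_i / sum of distances)` so nodes in small
components are down-weighted, and isolated nodes get closeness zero,
keeping the measure total. Betweenness and closeness are also divided by
`n - 1` (the convention adopted here; min/max scaling makes downstream
results invariant to the choice of normalizer, which the tests assert).
All three measures are min/max scaled, a constant measure scaling to all
zeros. A **hub** is a genus strictly above the per-measure empirical
quantile (type-7) on all three scaled measures; strictness avoids
inflating hub sets under ties. The default quantile is 0.90.

Hub sets from two networks are compared with the Jaccard index. Its null
distribution is obtained by drawing a uniformly random same-size set from
the shared genus universe against the fixed first set — for independent
uniform sets this is exactly the two-random-sets null, at half the cost —
with one-sided p-values carrying the `(1 + x)/(B + 1)` correction.
Because the index takes few distinct values at typical hub-set sizes, the
test is conservative: its attainable rejection level at nominal 0.05 is
below 0.05, and the acceptance suite checks the empirical rate against
the exact attainable level (hypergeometric-binomial closed form) rather
than against the nominal level.

Two core-microbiota definitions are implemented: the conventional one
(relative abundance above 0.1% in at least half the samples; both
thresholds are arguments) and the network-based one — hub membership at a
quantile tuned downward on a 0.005-step grid from 0.95 until the core
size matches the conventional core's size, preferring the larger
quantile on ties. `compare_cores()` reports average prevalence,
cumulative abundance on the count scale, and mean summed centrality, so
the two definitions can be contrasted per group.

## Graphlets and node roles

All connected 2-4-node induced subgraphs (9 graphlets) contribute 15
automorphism orbits; `graphlet_taxonomy()` derives them from scratch by
enumeration and brute-force automorphism search, ordered so that the
standard numbering (orbit 0 = degree; orbits 1, 4, 6, 9 = terminal
positions; 2, 5, 7 = chain interiors; 8, 10, 11 = cycle-bearing
positions) is reproduced. Counts come from a compiled exact enumerator
(`count_orbits()`, `O(n^4)` with pruning — ample for genus-level
networks); a deliberately simple pure-R enumerator
(`count_orbits_reference()`) serves as an independent oracle, and the
test suite additionally reconciles graphlet totals with `igraph`'s motif
counts. Four orbits (3, 12, 13, 14) are redundant given the others and
are dropped, leaving the 11-orbit graphlet degree vectors.

The **graphlet correlation matrix** (GCM) is the Spearman correlation
(average ranks) between the 11 orbit-count columns after appending a
pseudo-count row of ones, which prevents undefined correlations for
orbits absent from the network; a still-constant column yields `NA`,
never an imputed value. Two groups' GCMs are compared entry-wise with
Fisher's z-test, using `1/(n - 3)` variances with `n` = rows used for the
correlation (nodes + pseudo row; whether the pseudo row should count is
not settled, and at network scale the difference is negligible). Raw
p-values at 0.05 are the default; Benjamini-Hochberg across the 55
entries and the `1.06/(n - 3)` Spearman variance inflation are options.
Orbits are ranked by the number of significant difference entries they
participate in, and genera are mapped back to the selected orbits: the
top 25 genera per orbit (a practical, configurable cut), with the *focal*
genera being those in the top list of every selected orbit and the
occurrence `o` of a genus its mean count over the selected orbits. Ties
break lexicographically for determinism.

## Permutation comparison of networks

The null hypothesis is that a network property is equal in the two
groups. Group labels are randomly reassigned to samples (group sizes
preserved, reproducible stream per permutation index), the full
per-group pipeline — zero replacement, SparCC, t-test, lfdr or BH
sparsification, property computation — is rerun on each relabeling, and
the two-sided p-value is `(1 + #{|d_b| >= |d_obs|}) / (B + 1)`. Filters
are applied once to the full table before permuting, which keeps the
genus universe fixed and per-genus comparisons well defined;
re-filtering inside each permutation is intentionally not done. Failed
permutations are dropped and counted; more than 5% failures aborts the
test. The same machinery applies per genus to scaled centralities, with
genera isolated in a permuted network contributing zero centrality.

Zero replacement is per-sample and label-free, so it is computed once
and shared across permutations; the per-group SparCC step then works
from a cached log-composition matrix. This keeps the default 1000
permutations practical, and the type-I calibration study below feasible.

## The synthetic-data generator

The study data this pipeline targets are access-controlled, so the
package ships a generator whose draws stand in for them end to end. It
emulates genus-level 16S count tables: 87 genera by default (the typical
post-filter dimension of such tables), hundreds of samples, log-normal
read depths centered near 30,000 and truncated below at 10,000 (the
sample-filter floor), and a substantial zero fraction arising naturally
from multinomial sampling. The latent model is
logistic-normal-multinomial: a known positive-definite basis correlation
matrix with planted modular structure and optional boosted hub nodes
induces a Gaussian log-abundance vector per sample, which is
exponentiated, closed, and sampled at the drawn depth. This matches
SparCC's own generative assumptions, which is what makes parameter
recovery a meaningful validation target. If the planted matrix is not
positive definite it is repaired by eigenvalue clipping at `1e-6` and
re-standardization, and the ground-truth edge set is recomputed from the
repaired matrix (tolerance `1e-3`), so "truth" always refers to the
matrix actually simulated from.

What the generator does *not* emulate: taxonomic structure, over-
dispersion beyond the logistic-normal, batch effects, longitudinal
dependence, or read-level artifacts. Passing recovery tests on this
model therefore demonstrates correctness of the inference chain under
its own assumptions, not robustness to everything real stool samples do.

### Validation study conditions

The test and acceptance suites freeze these conditions:

* **SparCC recovery** — 50 genera in 5 modules (`p_within = 0.2`,
  `p_between = 0.005`), planted magnitudes uniform in `[0.4, 0.7]`, 20%
  negative, 500 samples. Reported: mean absolute error on planted edges
  (observed ≈ 0.04, required < 0.1) and the false-edge rate among
  lfdr-kept edges (observed 0, required ≤ 0.1).
* **Hub recovery** — 87 genera, 6 modules, five hubs with 30 extra edges
  each. Hub magnitudes are kept moderate (`[0.2, 0.35]`) because a node
  with 30 strong correlations forces a heavy positive-definiteness
  repair that would shrink the very structure being planted; moderate
  magnitudes are also the realistic regime for genus-level SparCC
  estimates. Reported: Jaccard overlap of `hubs(0.90)` with the planted
  hubs over three replicate datasets (observed 0.67-1.0, required
  ≥ 0.5).
* **Permutation type-I calibration** — two groups of 60 samples drawn
  from one 20-genus spec, `B = 200`, 500 replicates, tested on natural
  connectivity. That property was chosen for the calibration because it
  is a near-continuous function of the kept-edge set, so the permutation
  p-values are essentially tie-free and the rejection rate at 0.05 can
  be compared against its binomial 99% interval; a discrete property
  like edge density would be conservatively biased by ties. Problem
  sizes here (20 genera, 120 samples, 200 permutations) are the
  package's chosen desk-scale study design; the machinery is identical
  at full scale.
* **Jaccard-test null** — 2000 pairs of random 9-element sets from an
  87-genus universe, 1000 permutations each, compared against the exact
  attainable level of the discrete test.

## Numerical choices and degenerate inputs

* Correlations are clipped to `[-1, 1]`; basis variances floored at
  `1e-8`. A dissimilarity of exactly zero (a perfectly correlated edge)
  is floored at `1e-12` when used as a path length, since shortest-path
  algorithms require positive weights.
* An edgeless network has natural connectivity 0, undefined (NA)
  positive-edge percentage and path length, `Q = 0`, and one component
  per node. A sample of all zeros, an empty filter result, or a
  single-node network raise explicit errors.
* The t-test maps `|rho| = 1` to `p = 0`; the Fisher z-test flags
  infinite z-scores and reports `p = 0` (or `p = 1` when both
  correlations sit on the same unit bound).
* Determinism: every stochastic routine takes a seed; permutation
  streams derive per-iteration seeds as
  `(seed + 1000003 * b) mod (2^31 - 1)`.

## Known limitations

* SparCC assumes a sparse true correlation structure; dense planted
  networks (or hub rows with many strong edges) are attenuated both by
  the positive-definiteness repair in the generator and by the sparsity
  approximation in the estimator.
* The lfdr estimator needs a few hundred pairs to be stable; for small
  networks use the BH fallback.
* The t-distribution for SparCC estimates and the `1/(n - 3)` Fisher
  variance for Spearman correlations are approximations inherited from
  the field's standard toolchain.
* Orbit counting is exact but `O(n^4)`: comfortable to a few hundred
  nodes, not intended for networks of thousands of nodes.
* The permutation framework tests marginal property differences; it does
  not adjust for covariates, and a single combined differential network
  is deliberately out of scope.
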