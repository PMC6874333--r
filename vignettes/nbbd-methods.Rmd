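---
title: "Methods: differential-network feature selection for microbiome tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential-network feature selection for microbiome tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbbd)
```

## The model

The package is built around one hypothesis: taxa whose *ecological
interactions* differ between two phenotypes are candidate biomarkers even
when their marginal abundances do not. Concretely, a labeled OTU table is
split by phenotype, one association network is inferred per group over the
same taxa, and each taxon is scored by a measure of how much its position
in the two networks disagrees. The top-scoring taxa become the feature set
for an ordinary classifier whose held-out performance quantifies their
discriminative value.

Everything downstream of the table is graph work, so the assumptions enter
through two doors: how faithfully an association network can be estimated
from compositional, zero-inflated counts, and how sensitive the chosen
node score is to estimation noise. Both are discussed below, because they
bound what the method can deliver at realistic sample sizes.

## Network constructors and their tunables

All four constructors return a simple undirected `igraph` over taxon IDs.

**Proximity graph** (`build_proxi`). Distance
`d(u,v) = 1 - |r(u,v)|`; each taxon lists its `k_neighbors = 7` nearest
taxa and the union of lists gives the edges (so minimum degree is 7; a
`mutual` rule is available). By default `r` is computed on
log-transformed abundances: raw-scale Pearson on log-normal-like
abundance data is dominated by a few extreme samples, and the package
uses natural logs everywhere a log is needed. Ties in distance break
lexicographically so the graph is reproducible.

**SparCC** (`build_sparcc`). Works on per-sample fractions; zeros are
replaced by a pseudo-fraction (`pseudo_count` times half the smallest
nonzero fraction in the table). Because the estimate depends on fractions
only, rescaling any sample's row leaves it unchanged exactly — the
compositional invariance that motivates log-ratio methods. The basis
variances solve `diag(d) + A` against the row sums of the variation
matrix (with `A` the inclusion pattern); pairs whose estimated `|rho|`
exceeds `exclusion_threshold = 0.1` are excluded one per iteration (at
most `n_exclusion_iters = 10`) and the system re-solved, mirroring the
original algorithm's defaults; edges require `|rho| >= 0.3`. A singular
system falls back to Pearson on log fractions with a warning. Negative
basis-variance estimates (possible at small n) are floored at a tiny
positive value before the square root.

**Neighbourhood selection** (`build_mb`). Each taxon's clr abundance is
lasso-regressed on all others; nonzero coefficients define directed
neighbourhoods merged by OR (default) or AND. The penalty is picked per
graph from `lambda_grid` as the *smallest* value whose merged graph
density stays at or below `density_target = 0.05`, i.e. the densest graph
inside the sparsity budget. A "largest penalty under the density cap"
rule would be vacuous — density only falls as the penalty grows, so the
grid maximum always qualifies — which is why the rule is stated this way
around. Stability-based penalty selection (StARS-like) is out of scope;
the density rule is deterministic and desk-scale.

**RMT thresholding** (`build_rmt`). After a 25% prevalence filter,
Pearson correlations of log abundances are thresholded; the threshold is
scanned over `seq(0.30, 0.95, 0.01)` and the smallest value is kept at
which the eigenvalue spacing statistics of the thresholded matrix look
Poisson rather than correlated: eigenvalues of the submatrix on
non-isolated taxa are unfolded through a smoothing spline fitted to the
empirical cumulative count (degrees of freedom `min(10, n/4)`), and the
normalised nearest-neighbour spacings are tested against Exp(1) with a
chi-square over equal-probability bins (20 bins, fewer when spacings are
scarce; alpha 0.05). The unfolding and binning of the original ecology
pipeline are not published in executable detail, so this stage is a
reimplementation of the idea, not a bit-compatible port; grid, bin count
and alpha are exposed. If no threshold is accepted the grid maximum is
used, with a warning.

## Node scores

`compute_property` provides six per-node properties: betweenness
(unnormalised sum over unordered pairs), closeness in its reachable-set
form `(n-1)/sum d` (`n` counting the nodes that can reach `v`), average
neighbour degree, local clustering coefficient, node clique number and
core number. Degenerate nodes (isolated, or degree < 2 for clustering)
take the value 0 so differences stay finite; edge weights are ignored by
all six. `ntps_score(g_a, g_b, p)` is the absolute cross-network
difference on the shared vertex set — symmetric in its arguments, zero on
identical graphs, and undefined (excluded, not zero-filled) for taxa
present in only one network.

`cass_select` instead intersects the two networks' critical attack sets.
A removal ordering is built by repeatedly deleting the node with the
highest betweenness in the residual graph (ties lexicographic; a
disconnected input is reduced to its largest component with a warning;
after removals the residual graph is kept whole and betweenness is simply
per-component). Each resilience measure is evaluated at every non-empty
prefix and the minimising prefix is the attack set; on ties the smallest
prefix wins. Two consequences are worth stating:

* the empty set is *not* a candidate prefix. Since
  `|S| + Cmax(V-S) <= |V|` for every `S`, admitting it would never change
  an optimal value, but on dense graphs (already `K4`) it would win ties
  and return an empty integrity attack set, breaking the nesting
  `S_VAT ⊆ S_I ⊆ S_T` that the shared ordering otherwise produces and
  that the package asserts as a property;
* the greedy ordering is a heuristic. It is exact on stars (all three
  measures) and on paths for vertex attack tolerance and integrity, but
  *provably not* for tenacity on paths of five or more nodes: the 5-path
  optimum `{b, d}` (tenacity 1) is unreachable from any ordering that
  must start at the central node, where the greedy value is 1.5. The
  exhaustive oracle `brute_force_measure` (up to 16 nodes) pins both the
  equalities and this gap in the test suite; on random small graphs the
  greedy value agrees with the optimum in roughly nine cases out of ten
  and is an upper bound always.

The hybrid score multiplies random-forest importance by an NTPS score on
the shared taxa. No rescaling is applied before the product: both factors
are non-negative and only the induced ranking is consumed, but users
combining scores across runs should be aware the product inherits the
scale of each factor.

## The synthetic benchmark: what it emulates, and what it does not

`make_benchmark` is the package's study bed. Its defaults — 100 taxa, 10
planted differential taxa, 100 samples per group, sequencing depth
10,000, zero inflation 0.1, Erdős–Rényi base graph of mean degree 4,
precision weight `w = 0.3` — are fixed once here and used by the tests
and the acceptance script.

The latent model ties abundances to a graph: precision matrix
`I + w A` (shrunk toward the identity until positive definite), inverted
and converted to a correlation matrix; multivariate-normal draws are
exponentiated, multinomially resampled at fixed depth (compositionality),
and independently masked to zero (excess sparsity). Group B's graph
equals group A's except that every edge incident to a planted taxon is
removed and reattached: alternate planted taxa concentrate the reattached
edges (emerging hubs) while the others end up peripheral. The role flip
is deliberate — in a homogeneous random graph, reattaching a node's edges
to *uniformly* new partners leaves its centrality distribution unchanged,
so planted taxa would not actually be differential in any role-sensitive
property, defeating the purpose of a planted benchmark.

Two honest limitations follow from this design and are confirmed
numerically by the test suite and `scripts/acceptance.R`:

* **inference is noise-limited at these conditions.** Under `I + wA`
  with `w = 0.3` the marginal correlation of a truth edge cannot exceed
  about 0.3 (and positive-definiteness shrinkage pushes it to ~0.2 for a
  mean-degree-4 graph), while the largest of ~92 noise correlations per
  taxon at n = 100 is typically ~0.28. Truth edges sit at the noise
  floor, and the k-nearest-neighbour rule additionally pads every taxon
  to degree ≥ 7 with edges that differ freely between the two groups'
  estimates. Differential-betweenness precision@10 on inferred proximity
  networks therefore plateaus near 0.15–0.3 (≈ 0.5 would require either
  stronger latent correlations or substantially more samples, and even
  perfect network recovery caps near 0.6 under this rewiring);
* **the group difference is purely structural.** Planted taxa change
  their network role, not their mean abundance, so marginal methods
  (Kruskal-Wallis, and largely the random-forest importances) are close
  to chance on the benchmark, and classifiers trained on any small
  feature subset hover near AUC 0.5. This is what makes the benchmark a
  clean test of *network* scoring — the hybrid score still at least
  matches importance-only selection on small feature-selection subsets —
  but passing it says nothing about absolute classification performance
  on real cohorts, where biomarkers usually carry marginal signal too.

Also not modelled: realistic taxonomic naming, phylogenetic correlation,
uneven sequencing depth across samples, longitudinal structure.

## The evaluation harness

Features are always selected on the feature-selection subset (FSDS) only;
the classifier (a 500-tree random forest, seed-pinned) is trained on the
full training table restricted to those features and evaluated on
held-out samples — so a small FSDS stresses the *selector*, not the
classifier. FSDS chains are nested by construction (prefixes of one
seeded shuffle per class), and `experiment_grid` sweeps FSDS size ×
method × k ∈ {10, …, 60}, recording failed cells (for instance an empty
shared attack set) as status rows rather than aborting the sweep.
Metrics: ACC, Sn, Sp at a 0.5 probability threshold; MCC with the
zero-denominator-gives-zero convention; AUC as the midrank statistic
(missing on single-class test sets). The positive class defaults to the
lexicographically larger label.

## Numerical choices and degenerate inputs

Natural logs throughout; zeros replaced by a pseudo-count (counts) or
pseudo-fraction (SparCC) before logs. Correlations with a constant taxon
are defined as 0, with a warning, never NaN. All ranking ties break
lexicographically by taxon ID, which makes `select_top_k` deterministic
and monotone in k. Every stochastic stage takes an explicit seed and
restores the caller's RNG state. Problem sizes in the tests and the
acceptance script (benchmarks of 100 taxa and 25–100 samples per group,
20 seeds; 500 random graphs of ≤ 7 nodes for the exhaustive oracle; 200
random graphs of ≤ 30 nodes for the nesting property) were chosen so the
full suite completes in a couple of minutes on a laptop while keeping the
Monte-Carlo error of the reported means small relative to the margins
being asserted.
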