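---
title: "Inter-module coupling analysis: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-module coupling analysis: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modcoupler)
```

## The problem

A multi-ingredient therapy perturbs a disease system through many weak
handles rather than one strong one. Representing the disease gene set and
the drug putative-target set as protein association networks, dissecting
each into dense modules, and quantifying which module pairs are coupled
turns the vague notion of a "shotgun-like" action mode into three concrete
statistics: a per-pair significance test, a per-pair coupling score, and a
pathway-level bridgeness profile. This vignette explains what each stage
assumes, which knobs matter, and where the method's limits are.

## Networks

`build_network()` induces a member set on an interaction table, keeping
edges with both endpoints in the set and confidence at or above a cutoff.
Confidences are canonicalised to [0, 1] (`read_edge_table()` accepts both
unit scores and STRING-style 0–1000 integers); duplicate unordered pairs
keep the maximum confidence, a conservative merge consistent with STRING's
combined-score semantics. The default cutoffs — 0.4 for the disease
network, 0.7 for the drug network — trade breadth against reliability in
the conventional way: a permissive disease scope, a strict target scope.
Cutoff comparisons are inclusive (`>=`); a `strict` flag switches to `>`
for users who read "more than" literally. Members with no qualifying
interaction are reported in `$isolated` and excluded from clustering, not
silently dropped.

`merge_networks()` forms the union graph: both node sets, both edge sets
(max weight on duplicates), plus background interactions joining a
disease-side node to a drug-side node at or above `cross_cutoff`. The
cross cutoff defaults to 0.7, the stricter of the two build thresholds;
it is deliberately a prominent parameter because the cross edges are what
the coupling statistics measure, and the appropriate confidence for them
is a scientific choice, not a formality.

## MCODE

`find_modules()` reimplements the molecular complex detection algorithm.
Each vertex is weighted by `k * density` of the highest k-core of its
closed neighborhood (density of a simple graph = 2E / V(V−1)); vertices
below the degree cutoff weigh 0. Complexes grow breadth-first from the
highest-weighted unvisited seed, admitting neighbors whose weight is at
least `seed_weight * (1 - node_score_cutoff)`; included vertices are
marked visited, so one clustering yields pairwise disjoint modules.
Candidates lacking a 2-core are discarded; haircut iteratively removes
members with intra-module degree below 2. Module score is intra-module
density times size.

Defaults are the canonical published MCODE values: degree cutoff 2, node
score cutoff 0.2, k-core 2, haircut on, fluff off, maximum depth 100.
Fluff stays off so modules remain disjoint — the coupling score's
shared-node term should measure overlap *between* the disease and drug
clusterings, not within one. All ties (seed choice, expansion order, equal
scores) break lexicographically by symbol, making the clustering invariant
to node and edge insertion order. Edge weights are ignored by design:
confidence thresholding happens upstream, and MCODE is a topological
algorithm.

One behavior worth understanding: the expansion tolerance is relative to
the *seed* weight. Two dense regions whose vertex weights lie within that
20% band of each other will be merged into one module whenever any edge
bridges them, because the expansion walks across the bridge and every
vertex on the far side passes the threshold. Planted cliques of sizes 12
and 10 (vertex weights 11 and 9; 9 ≥ 0.8 × 11) sitting in a sparse random
background are merged as soon as a single background edge joins them,
which at a background edge probability of 0.02 happens for most random
instances. This is faithful MCODE behavior, not an artifact of this
implementation; separation is only guaranteed when module weights differ
by more than the tolerance (e.g. cliques 12/8/6), and the package's
recovery tests are built around that distinction. Users clustering
networks with near-equal-density communities should lower
`node_score_cutoff` deliberately rather than rely on the default.

## Inter-module statistics

For modules $M_x$ and $M_y$ inside the union graph, `pair_connectivity()`
counts shared nodes $t$, candidate pairs $n$ (unordered pairs with one
endpoint in each module, each counted once, so
$n = |M_x||M_y| - t - \binom{t}{2}$ — shared nodes pair with every other
member but never with themselves), and observed connections $x$.
Intra-module edges never count. The per-pair significance is the exact
hypergeometric upper tail

$$p = \sum_{k=x}^{n} \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}},$$

where $M = \sum x_i$ and $N = \sum n_i$ accumulate over all pairs in
scope. The null model is therefore conditional: the network's total stock
of inter-module connections is dropped uniformly into the candidate
slots. The default scope is disease-by-drug pairs only
(`cross_origin_only`); `all_pairs` accumulates over every module pair,
which is the appropriate scope for a within-network module map. The tail
sum is evaluated through R's hypergeometric distribution functions, which
work in log space; a brute-force enumeration oracle in the test suite
verifies all instances with $N \le 12$ to 1e-12.

Significant pairs ($p \le 0.05$, inclusive, configurable) carry the
coupling score $CS = 2t + \sum a_{ij}$ over the cross edges, each
unordered edge counted once — including edges both of whose endpoints are
shared nodes, which is the convention that keeps $x \le n$ provable and
CS exactly additive (one more cross edge of weight $w$ raises CS by $w$;
one more shared node raises it by 2). No multiple-testing correction is
applied by default, matching common practice for this statistic's
exploratory use; `p_adjust = "BH"` is available.

Because the p-values are discrete, their null distribution is
sub-uniform: the exceedance rate at level $\alpha$ equals the largest
attainable p-value atom at or below $\alpha$, which is at most $\alpha$.
The calibration test resamples the conditional null 2,000 times and
checks the pooled exceedance rate against $\alpha$ plus three binomial
standard errors.

## Direct targets and enrichment

`direct_targets()` intersects the two symbol sets; `localize()` places the
intersection within the disease modules and reports percentages of the
target total, rounded half-up to two decimals (so 12 of 28 prints as
42.86%, and the 12 + 4 in the two core modules as 57.14%). Rounding
half-up rather than half-even matches how such shares are conventionally
printed.

`enrich()` is a one-sided hypergeometric overrepresentation test
(equivalent to one-tailed Fisher) against the annotation background —
by default the union of all gene-set members, overridable. Enrichment
records can be rolled up by KEGG-style category codes
(`categorize()`), and `grouping_preset("signal_transduction")` pools
categories 3.2 and 3.3 into one "signal transduction-related" group; the
pooling is a named, optional preset, never silent behavior.
`bridgeness()` intersects the significant-pathway unions of a disease
module group and a drug module group.

The packaged fixture behind `hljdd_bridgeness_fixture()` carries 14
literature-reported pathway rows (ids, categories, both sides' p-values
and hit genes) verbatim. Those p-values are metadata, not recomputation
targets: the enrichment tool and background that produced them were not
published, so this package treats them as fixed inputs for exercising
bridgeness and category profiling.

## Synthetic data

`make_planted_network()` draws every node pair independently — within a
planted module with probability `p_in`, elsewhere `p_out` — with weights
uniform on [0.4, 1] by default, mirroring a confidence floor of 0.4. Pairs
are drawn in a fixed canonical order, so a seed fully determines the
output on any platform. `make_paired_networks()` couples two such
universes: a chosen number of shared nodes placed inside designated
planted modules (direct targets concentrate in core disease modules, and
the generator emulates that), plus a background table carrying an exactly
realised cross-edge budget between designated module pairs.

What the generator does *not* emulate: degree heterogeneity and hub
structure of real interactomes, correlated annotation (real pathways
overlap real modules non-randomly), study-bias-driven confidence
patterns, and identifier noise. Passing tests on planted scenarios
therefore demonstrate correctness of the algorithms under their own
assumptions, not performance on real proteomes.

Test and vignette problem sizes (40–150 nodes, module sizes 5–12,
2,000-resample nulls) were chosen as the smallest scales at which every
statistic is exercised away from its boundary; the dataset-scale counts
reported in the motivating case study (hundreds of proteins, thousands of
interactions, 15 + 13 modules, 28 direct targets) depend on live database
versions and unpublished clustering parameters and are not reproducible
from first principles here.

## Numerical and degenerate-input choices

- Hypergeometric arguments are validated (`0 <= x <= n <= N`,
  `0 <= M <= N`); impossible tail terms contribute zero; `x = 0` returns
  exactly 1.
- An edgeless network clusters to an empty module list; fewer than two
  modules yield an empty modular map; an empty bridgeness overlap is a
  valid report.
- Self-loops in interaction tables are dropped with a warning; malformed
  rows and out-of-range scores fail with the line number.
- All orderings (module ranks, map edges, serialized tables) are total
  and deterministic: score, then size, then lexicographic member/id
  tie-breaks.
- Serialized numerics use full precision (`%.17g`), so write/read round
  trips are exact.

## Limitations

- The conditional null places connections uniformly into candidate slots;
  it is blind to edge weights and to degree structure within modules. A
  degree-preserving rewiring null would be stricter and is out of scope.
- CS is not normalised for module size; comparing CS across pairs of very
  different sizes should lean on the p-value instead.
- Symbol matching is exact and case-sensitive; no alias or ortholog
  resolution is attempted, so inputs must share a namespace.
- MCODE's seed-relative expansion tolerance merges near-equal-weight
  dense regions connected by even one edge (see above).
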