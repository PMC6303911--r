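---
title: "Network-based enrichment of metabolite lists: model and methods"
author: "netmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based enrichment of metabolite lists: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmet)
```

## The problem

Classical over-representation analysis reduces a metabolomics experiment
to a flat list of pathway p-values. That list is hard to interpret:
pathways overlap, cross-talk, and say nothing about *how* the affected
metabolites reach them. `netmet` instead scores every entity of a
five-level knowledge graph — pathways, modules, enzymes, reactions and
compounds, linked by curated annotations — and reports a connected
sub-network that traces the input metabolites up to the relevant
pathways through the intermediate biochemistry.

## The knowledge graph

The graph is undirected, unweighted and simple. Edges join entities of
different levels only; the canonical build derives them from five KEGG
annotation families (pathway–module, pathway–enzyme, module–enzyme,
enzyme–reaction, reaction–compound). Global "overview" maps (pathway
numbers 011xx/012xx) are removed before anything else: they would link
most of the metabolism into one node. The build is then reduced to its
largest connected component, which makes the diffusion system below
non-singular; ties in component size break towards the component
containing the smallest node id, so builds are reproducible.

A directed *upward view* orients every edge from the lower level to the
higher one (compound → reaction → enzyme → module → pathway). Heat
diffusion works on the undirected graph; PageRank walks the upward
view.

## Scoring by propagation

### Heat diffusion

Each input compound injects one unit of heat; a virtual boundary node
held at temperature zero and attached to every pathway absorbs it. With
`L` the combinatorial Laplacian of the augmented graph, the equilibrium
temperatures solve the grounded system

$$ L_g\,T = G, $$

where `L_g` deletes the boundary row and column and `G` is the 0/1
indicator of the input compounds. Because attaching one shared boundary
node to all pathways adds exactly 1 to each pathway's degree and
nothing else, `L_g` equals the graph Laplacian plus a unit diagonal on
pathways — a per-pathway boundary attachment is mathematically
identical for the grounded solve, so the single grounded node is used.
All temperatures are non-negative, adding an input compound can only
raise them (the inverse of a grounded Laplacian is entrywise
non-negative), and the total flow into the boundary — the sum of
pathway temperatures — equals the input size exactly; the test suite
checks both properties against a dense from-first-principles solve.

Diffusion being undirected, heat leaks back down from reactions and
enzymes to compounds that were *not* in the input. That is a feature:
intermediate metabolites that sit between the affected ones surface in
the ranking.

### Personalized PageRank

The second scorer is the stationary distribution of a random walk on
the upward view that restarts, with probability `1 - damping`,
uniformly into the input compounds. Pathways have no upward arcs, so
their walk mass must go somewhere: `netmet` redistributes it uniformly
over all nodes, the classical PageRank convention. This choice is
deliberate. Redistributing to the restart distribution instead — the
other common convention — makes the transition kernel depend on the
input, and the stationary distribution is then `Av / sum(Av)`, which is
*not* linear in the restart vector `v`. With a fixed kernel the score
is exactly linear in `v`, sums to one by construction, and tends to the
restart distribution as damping goes to zero; all three contracts are
tested at solver precision, with a dense full-kernel solve and an
independent power iteration as cross-checks. The damping default is
0.85, the de-facto standard.

### Hypergeometric reference

For comparison, `method = "hypergeom"` applies Fisher's exact test per
pathway: with `m` compounds overall, `m_P` of them annotated to pathway
`P` (annotation = having an upward path to `P`) and `x` of the `n`
input compounds among those, the score is the upper tail
`Pr(X >= x)`, `X ~ Hypergeom(m, m_P, n)`. It is already a p-value and
skips the permutation normalization; only pathway nodes are ranked.

## Normalization: from raw scores to p-scores

Raw propagation scores are strongly biased by topology — hubs and
high-level nodes run hot no matter the input. Scores are therefore
normalized against the *permutation null*: an input of the same size
`n` drawn uniformly without replacement from all `m` compound nodes.

Both scorers are linear in the input indicator, `score_i = sum_j K_ij
y_j`, where the column `K_{·j}` is the score vector for the singleton
input `{j}` (for PageRank divided by `n`, matching the uniform restart
weights). Exact null moments follow from sampling-without-replacement
algebra:

$$ \mu_i = \frac{n}{m} \sum_j K_{ij}, \qquad
   \sigma_i^2 = \frac{n(m-n)}{m(m-1)} \sum_j (K_{ij} - \bar K_i)^2. $$

The suite verifies both against exhaustive enumeration of all `C(m, n)`
inputs to 1e-10. The parametric (`approx = "normality"`) p-score is the
upper normal tail `1 - Phi((score - mu)/sigma)`; large scores map to
small p-scores. Nodes with `sigma = 0` cannot be distinguished from the
null and get p-score 1 (conservative; a relative tolerance of 1e-12
guards against numerical zeroes).

`approx = "simulation"` instead redraws `niter` random inputs (default
1000), recomputes raw scores — one sparse multi-right-hand-side solve,
not `niter` separate solves — and reports the add-one estimator
`(1 + r)/(1 + niter)`, which never returns zero. Fixed seeds give
byte-identical results.

The normal approximation is good when a node's null score aggregates
many comparable influence terms. On small graphs with small inputs the
null of a compound-level node is a two-point mixture (the node is in
the input or not) and the approximation degrades; the consistency check
between the two routes therefore runs at `n/m ≈ 0.4` on a 100-node
graph, where the mixture modes merge and the median per-node
discrepancy is around 0.01–0.02. p-scores are rankers, not calibrated
hypothesis tests, and are deliberately not multiplicity-adjusted.

## Reporting

`select_nodes()` keeps nodes with p-score at or below `threshold`
(default 0.05) and cuts to the `nlimit` best (default 250; the CLI
exposes the same default). The full ordering — p-score ascending, raw
score descending, id ascending — makes the cut deterministic under
ties. The reported sub-network is the induced subgraph on the
selection, exported as TSV tables (all nodes; enzymes with their gene
annotations) and GraphML.

An optional filter removes connected components of the selection that
are no larger than chance would produce. At database-build time,
`build_cc_null_table()` samples `reps` uniform `k`-node induced
subgraphs over a size grid (default {10, 20, 50, 100, 250, 500},
clipped) and records the largest component order; a component of order
`r` in a selection of size `k` survives only if the empirical
`Pr(max component >= r | k)` is at most `alpha_cc` (default 0.05; the
filter is off by default). Off-grid `k` uses the nearest grid point, or
optional log-linear interpolation. The component order is tested
against the *maximum*-component null — the natural reading when the
question is "could a blob this large arise by chance?".

## The synthetic generator

All scoring code is testable offline through `generate_graph()`, which
draws random bipartite edges for the same five link families the KEGG
builder assembles, then reduces to the largest component. Defaults
mirror the level proportions of published organism builds at roughly
1/20 scale — 16 pathways, 10 modules, 55 enzymes, 240 reactions, 175
compounds — with a sparse upper hierarchy (modules belong to about one
pathway, enzymes to at most a few modules or pathways, compounds to
about two reactions). Those densities matter: they leave each pathway
upward-reachable from only ~10–30% of compounds, as in the real
database. If the upper levels are dense, reachability saturates, every
pathway "contains" nearly every compound, and a planted signal becomes
indistinguishable from noise.

`generate_planted_input()` emulates a coherent perturbation: a fraction
`1 - noise_fraction` of the input is drawn from the compounds with an
upward path to one planted pathway, the rest uniformly from the
remaining compounds. By default the planted pathway is the most
specific one that can supply the signal — a focused pathway is the
meaningful notion of "planted"; a near-global one cannot be recovered
even in principle. Under the default graph, inputs of size 8 with 25%
noise recover the planted pathway in ≥ 90% of seeds at threshold 0.05.

What the generator does *not* emulate: the heavy-tailed degree
distribution of real metabolism (currency metabolites such as ATP and
water touch hundreds of reactions), compound labels and masses, enzyme
multi-functionality patterns, and release-to-release drift of KEGG
annotations. Passing tests on synthetic graphs therefore validate the
algebra and the pipeline, not the biology of any particular KEGG
release; real-data results remain release-dependent.

## Numerical choices

* Sparse direct solves (`Matrix`) for the grounded system and the
  PageRank fixed point; the power iteration (tolerance 1e-12, cap
  10,000 iterations) exists as an independent route used in testing.
* The per-compound influence matrix costs one solve per compound node;
  this is fine at desk scale (thousands of compounds), and
  `approx = "simulation"` is the fallback for very large graphs.
* Monte Carlo draws, the component-null table and the CLI all take
  explicit integer seeds; a fixed `RunConfig` reproduces every output
  file byte-for-byte.
* Problem sizes used by the automated checks: dense-oracle equivalence
  on 100 graphs of ≤ 200 nodes; moment enumeration at `m ≤ 12`,
  `n ≤ 4`; the parametric/simulation comparison on a ~100-node graph
  with 10^4 permutations; planted-signal recovery on 50 default graphs
  (~450–500 nodes).

## Limitations

* Input is a qualitative compound list; abundances and effect sizes are
  not used.
* p-scores rank entities; they are not FDR-controlled significance
  statements.
* The KEGG builder requires network access (or a pre-fetched cache) and
  inherits whatever the current KEGG release contains; two releases can
  legitimately disagree.
* The interactive exploration of results is out of scope; exports are
  static files meant for Cytoscape or downstream scripting.
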