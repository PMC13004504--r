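---
title: "Targeted degree-preserving rewiring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted degree-preserving rewiring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrewire)
```

## The problem

Small social networks — friendship, collaboration, contact, trust and
communication networks of a few hundred nodes — tend to share a family
resemblance: skewed degree distributions, positive degree assortativity,
high clustering and short geodesics. These properties are not free to vary
independently: fixing the degree sequence and pushing one property can drag
others along, or block them. `netrewire` makes that dependence observable.
It holds the degree sequence fixed and manipulates exactly one property at
a time by rewiring edges, while measuring a panel of other properties along
the way. Three separate algorithms respectively *increase degree
assortativity*, *increase the mean local clustering coefficient*, and
*decrease the mean geodesic distance*.

The toolkit is deliberately degree-sequence-centred: an empirical network
enters an experiment only through its degree sequence, from which random
starting networks are drawn with the configuration model. Any property
movement observed along a trajectory is therefore attributable to wiring
pattern alone, never to degree changes — the degree mean and degree Gini
columns of every trajectory are constant by construction, and the test
suite asserts the multiset of degrees is identical after every single
attempt.

## The measured panel

For each snapshot, `measure_all()` records:

* **degree assortativity** `r`: the Pearson correlation of the degrees at
  the two ends of every edge, taken over both orientations. On
  degree-regular graphs the correlation is undefined; the package returns
  `NA`, which serializes as an empty CSV cell.
* **mean local clustering** `C`: the per-node fraction of neighbour pairs
  that are themselves connected, averaged over *all* nodes. Nodes of degree
  below 2 contribute 0 rather than being dropped; this keeps the mean
  defined on every graph and is the common convention.
* **transitivity** `T`: `3 * triangles / connected triples`, defined as 0
  when there are no triples. `C` and `T` summarize the same triangles at
  different levels and need not move together.
* **mean geodesic** and **diameter** from the all-pairs shortest-path
  table, which is computed once per snapshot and shared with closeness.
* **closeness**, **betweenness** and **eigenvector centrality**, each
  reported as a mean and a Gini coefficient. Closeness is the inverse form
  `(n-1)/farness` — the *reciprocal* of the average distance — so that
  shortening paths raises closeness; with the literal "average path length"
  convention every reported direction would flip. Betweenness uses
  endpoint-excluded fractional counting normalized by `(n-1)(n-2)/2`, which
  keeps values in `[0, 1]` and near zero for typical nodes on
  hundred-node graphs. Eigenvector centrality is normalized to unit
  Euclidean norm and computed by power iteration on `A + I` (the shift
  leaves the principal eigenvector unchanged and guarantees convergence on
  bipartite-like structures) to a relative tolerance of `1e-10` with an
  iteration cap of `1e5`.
* the **Gini coefficient** is used as the variation measure throughout
  because centrality distributions are typically far from normal. It is
  computed with the `O(n log n)` sorted form; the test suite requires exact
  agreement with the definitional `O(n^2)` double sum, and the exhaustive
  small-graph suite checks every metric above against independent
  brute-force oracles (definitional Pearson, neighbour-pair enumeration,
  Floyd–Warshall distances, path-count betweenness, dense eigensolver) on
  *all* labeled connected graphs with up to 6 nodes and samples with 7.

## Starting networks

`configuration_model()` realizes a degree sequence by uniform stub
matching and then simplifies: self-loops are removed and parallel edges
collapsed. We chose simplification over rejection-sampling simple graphs
because it always terminates and its slight degree deficit mirrors the
small gaps between empirical and randomized mean degrees seen in practice;
for sequences whose maximum degree is small relative to `n` the mean
relative deficit is under 5% (asserted at `n = 200` in the tests). The
giant component — with ties broken deterministically towards the component
containing the smallest original vertex id — is the starting network;
rewiring preserves connectivity thereafter, so all geodesic-based measures
stay defined.

## The three algorithms

All three share a skeleton: select candidate edges at random, evaluate a
degree-preserving swap, and commit it only if it moves the target property
strictly in the desired direction without disconnecting the graph or
creating a duplicate edge. Rejected proposals are reverted exactly.

**Assortativity.** Two disjoint edges are drawn uniformly. Ranking the
four endpoint degrees, the proposed pairing connects the two
highest-degree nodes together and the two lowest together — by the
rearrangement inequality the pairing that maximizes the sum of
endpoint-degree products. Because a degree-preserving swap leaves the
marginal moments of the endpoint-degree distribution untouched, the change
in `r` has the same sign as the change in that product sum; the package
commits only on a strict product-sum increase, which guarantees `r` rises
monotonically (this sign link is itself asserted on a thousand committed
swaps in the tests).

**Clustering.** A node `A` with degree at least 2 is selected uniformly;
two of its incident edges give neighbours `u` and `v`; one further uniform
step beyond each gives a simple five-node path `p–u–A–v–q`. The end edges
`(p,u)` and `(v,q)` are broken, the central triangle is closed with
`(u,v)`, and `(p,q)` restores the degrees of the outer nodes. Edge
breaking can destroy existing triangles, so the mean local clustering
coefficient is recomputed and the rewire is committed only if it strictly
increased.

**Geodesic.** A node pair is sampled with probability proportional to its
current distance — weighting rather than always taking the most distant
pair avoids starving intermediate distances — and one neighbour of each
endpoint is sampled with probability proportional to degree. The two
edges to those neighbours are replaced by a direct shortcut between the
pair plus an edge between the neighbours. The all-pairs distance table
must be recomputed to evaluate the proposal (this is what makes geodesic
attempts an order of magnitude more expensive than the other two), and the
rewire is kept only if the mean geodesic strictly decreased.

Ties are rejected in all three algorithms. Treating a no-change proposal
as a failure keeps trajectories strictly monotone in the target and makes
the convergence accounting below conservative. Degenerate selections — the
two sampled edges share a node, no five-node path exists, the sampled
neighbours coincide — also count as failed attempts rather than being
silently resampled: they are wasted proposals, and the stopping rule is
about the rate of wasted proposals.

## The controller

Each run has three parameters beyond the algorithm:

| parameter | default | meaning |
|---|---|---|
| `window` | `0.2 M` (assortativity, clustering); `0.1 M` (geodesic) | attempts between snapshots and convergence checks |
| `convergence` | 0.9 | stop when a completed window's success rate falls below `1 - convergence` (10%) |
| `max_attempts` | `10 M` (assortativity, clustering); `M` (geodesic) | hard cap |

`M` is the edge count of the starting network. The geodesic algorithm gets
the smaller window and cap because each of its attempts costs two
all-pairs shortest-path computations. The property panel is measured at
attempt 0 and at every window boundary; a terminal snapshot is always
recorded even when the cap interrupts a window. Given a seed, a run is
exactly reproducible; the experiment orchestrator derives every
per-network and per-run seed deterministically from one master seed.

## Synthetic degree sequences

`synth_degree_sequence()` draws lognormal degrees calibrated in closed
form: a lognormal with log-sd `sigma` has Gini `2*pnorm(sigma/sqrt(2)) - 1`,
so the target Gini `g` gives `sigma = sqrt(2) * qnorm((g+1)/2)` exactly,
and the log-mean is set so the continuous mean equals the target mean
degree. The lognormal was chosen as the single skewed family precisely
because this closed form makes the calibration testable (the suite checks
a sample Gini within 0.02 of target at `n = 10^4`); a Poisson family
covers low-variation sequences. Draws are rounded and clamped to a minimum
degree of 1; if rounding and clamping would distort the mean by more than
20% the specification is rejected as infeasible rather than silently
shifted. Odd degree sums are repaired by incrementing one uniformly chosen
node — incrementing rather than decrementing so the minimum degree of 1
survives.

`reference_sequence_specs()` records the size, mean degree and degree Gini
of seven published small social networks (101–610 nodes, mean degree
3.7–43, degree Gini 0.25–0.53); sequences generated from those triples
produce configuration-model giant components whose densities fall in the
published 0.006–0.148 range, which is the sense in which the synthetic
fixtures "emulate" the empirical ones. They emulate *only* those three
moments: real social-network degree sequences carry higher-order structure
(discreteness spikes, truncation, multimodality) that a two-parameter
lognormal cannot reproduce, so passing tests on synthetic sequences show
the algorithms behave correctly and effectively across this size/inequality
range — not that any particular empirical network would trace the same
trajectory. Users with real edge lists can feed them directly
(`read_edge_list()` → `degree_sequence_of()`) and rerun everything.

## Problem sizes and numerical choices

The worked examples and checks in this package use a 150-node lognormal
sequence (mean degree 5.5, Gini 0.25 — the scale of a classroom contact
network) for the assortativity and clustering algorithms, and a sparse
600-node sequence (mean degree 3.7, Gini 0.53 — the scale of a sparse
email network) for the geodesic algorithm, whose behaviour is only
interesting when geodesics start long. At these sizes a full
assortativity or clustering run takes a few seconds and a full geodesic
run under a minute on one core.

Other numerical choices, made once and kept:

* Strict inequalities decide commits; no tolerance slack is applied, since
  clustering and geodesic means are ratios of exact integer counts and the
  product-sum criterion is integer arithmetic.
* Connectivity after a tentative swap is decided by a single traversal;
  the swap is reverted on failure.
* The geodesic distance table is maintained by full recomputation per
  evaluation rather than incremental updates — at these sizes the BFS
  sweep is cheap and recomputation cannot drift.
* The giant-component tie-break and the first-appearance node relabelling
  in `read_edge_list()` exist purely to make results reproducible; both
  retain the original identifiers as vertex attributes.

## Known limitations

* Undirected, unweighted, simple graphs only; bipartite structure is not
  modelled (a one-mode projection must be made before extracting a degree
  sequence).
* Each algorithm moves its target in one direction only (raise `r`, raise
  `C`, lower geodesics); the opposite directions and simultaneous
  multi-property targeting are out of scope.
* Geodesic rewiring is effective only when the starting mean geodesic
  leaves room to shrink; on dense networks with geodesics near 2 most
  proposals fail and runs converge quickly — which is informative, not a
  malfunction.
* Trajectories explore the property space reachable by *this* proposal
  distribution; stalled progress bounds what these algorithms reach, not
  what is combinatorially possible for the degree sequence.
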