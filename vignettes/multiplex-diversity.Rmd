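---
title: "Measuring the diversity of multiplex networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the diversity of multiplex networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multidiv)
```

## The model

A multiplex network is a collection of `M` simple undirected graphs (layers)
on one shared, labeled node set of size `N`. `multidiv` asks two questions:
how far apart are two layers, and how much diversity does a set of layers
(or one node's per-layer connectivity) carry as a whole.

### Layer distance

Each node `i` in layer `p` is summarized by two distributions:

* its *node distance distribution* (NDD): the fraction of the other `N - 1`
  nodes at each shortest-path distance `1, ..., N-1`, plus one aggregate
  `UNREACHABLE` bin;
* its *transition profile*: the one-step random-walk distribution, `1/k` on
  each of its `k` neighbors, or a point mass on a reserved `<INACTIVE>`
  outcome when `k = 0`.

The node difference is

$$\mathcal{D}_i(p,q) = \frac{\sqrt{J(\mathcal{N}_i^p, \mathcal{N}_i^q)} +
  \sqrt{J(T_i^p, T_i^q)}}{2\sqrt{\log 2}},$$

with `J` the Jensen-Shannon divergence in nats, and the layer difference
`LD(p,q)` is its mean over all `N` nodes. Both live in `[0, 1]`. This is a
distance between *labeled* graphs: two isomorphic but differently wired
layers are at positive distance, which is the desired behavior when node
identity is meaningful (the same airport in two airlines' route maps, the
same protein in two assays).

Three representation choices deserve a note, because the underlying
definitions do not pin them down:

* **NDD normalization.** The NDD excludes the node itself (no `d = 0` bin)
  and divides by `N - 1`. With this convention a node connected to every
  other node carries all its mass on finite bins, an isolated node is a point
  mass on `UNREACHABLE`, and the advertised extreme
  `\mathcal{D}_i = 1` — isolated in one layer, reaching all nodes in the
  other — holds *exactly*, because the two profiles then have disjoint
  support and both divergences reach `log 2`.
* **The `<INACTIVE>` sentinel.** A degree-zero row of the degree-rescaled
  adjacency would be all zeros and the divergence would be undefined.
  Routing the mass to an outcome disjoint from every node label keeps the
  profile a probability distribution and again makes the extreme case exact.
* **`UNREACHABLE` is a single bin.** Only reachability matters; "how far
  unreachable" has no meaning in a disconnected graph.

A node inactive in both layers has identical profiles in both (the same two
point masses), so its difference is 0, and it *is* counted in the `LD`
average — `LD` stays a plain mean over the shared node set.

### Diversity

Given pairwise distances `D` on a set `S`, the element-to-set distance is
`D(g, S) = min over s in S of D(g, s)`, and the diversity value is the
recursion

$$U(S) = \max_{s \in S}\{\,U(S \setminus s) + D(s, S \setminus s)\,\},
\qquad U(\{s\}) = 0 .$$

Unrolled, `U(S)` is the maximum over all elimination orderings of the summed
element-to-remainder distances. It is monotone under set inclusion, satisfies
`U(S \cup g) \ge U(S) + D(g, S)`, is unchanged by duplicating an element
(a zero-distance twin), and scales linearly with the distances. The test
suite checks all four properties on a thousand random matrices.

## Algorithms

**Exact dynamic programming** (`diversity_exact()`): a bottom-up table over
all `2^K` subsets, written in C++ — the normative solver. The elimination
order is recovered by backtracking the argmax chain. The table caps `K` at
`dp_limit` (default 20, i.e. a 2^20-entry table; configurable via
`options(multidiv.dp_limit = )`).

**Greedy lexicographic elimination** (`diversity_greedy()`): repeatedly
remove the element whose sorted vector of distances to the remaining
elements is lexicographically smallest, accumulating its minimum distance.
This is the scalable route for large `M` and it defines the diversity
ordering (least contributing removed first). The vector rule — rather than
the bare minimum distance — is what breaks the tie in the bundled worked
example the right way: elements `a` and `c` share the smallest pairwise
distance 0.214, and `c` is removed first because its remaining distances
(0.580, 0.804) precede `a`'s (0.697, 0.786).

### Greedy and exact values can differ

Every greedy elimination is one feasible ordering, so greedy ≤ exact always.
Equality, however, is a property of the distance matrix, not a theorem: on
uniform-random symmetric matrices the two agree for `K = 3` (provably:
with `d12 ≤ d13 ≤ d23`, both give `d12 + d23`) but diverge on roughly a
fifth of matrices at `K = 4` and more than half at `K = 8`, by up to tens of
percent. A minimal counterexample is

```{r}
m <- matrix(c(0, .604, .807, .730, .536,
              .604, 0, .973, .379, .552,
              .807, .973, 0, .829, .619,
              .730, .379, .829, 0, .862,
              .536, .552, .619, .862, 0), 5, 5,
            dimnames = rep(list(letters[1:5]), 2))
c(exact = diversity_exact(m)$value, greedy = diversity_greedy(m)$value)
```

The myopic rule cannot see that removing a slightly-less-close element now
preserves a much larger remainder later. No alternative myopic rule we
tested (ranking by the remaining set's distance vector instead of the
removed element's) closes the gap. The package therefore treats the DP as
the definition and the greedy as a lower-bound heuristic; `method = "auto"`
uses the DP whenever the set fits under `dp_limit`. On distance matrices
arising from small, structurally related layers (such as the bundled
fixtures) the two routinely agree, which is why the discrepancy is easy to
miss on worked examples.

### Conventions in the report

A `diversity_report` lists `K - 1` removals. The last surviving element has
no increment of its own; the final pair distance is assigned to the
second-to-last removal, so increments always sum to `U`. An element's
*contribution* is its increment divided by `U` (the survivor contributes 0);
contributions sum to 1. These are reporting conventions, not part of the
recursion.

**Layer reduction** (`reduction_curve()`) removes elements in greedy
elimination order and re-measures `U` of the retained set at every step
(exactly, when the retained set fits under `dp_limit`). Because removing `g`
loses at least `D(g, S)`, the curve is non-increasing; the loss fraction
`1 - U_retained / U_full` runs from 0 to 1. Layers are only ever removed,
never merged into aggregate layers that exist in no observation.

## Numerical choices

* Entropies in nats; the `2 sqrt(log 2)` normalizer matches that convention.
  (Bits with normalizer 2 would be equivalent; one convention is fixed for
  reproducibility.)
* Jensen-Shannon values are clamped to `[0, log 2]` to absorb rounding at
  the disjoint-support boundary, so the `D_i = 1` extreme is exact.
* Distribution sanity checks tolerate `1e-9` on the total mass; equality
  assertions on diversity values use `1e-9`; oracle comparisons in the test
  suite use `1e-12`.
* Argmax ties in the DP backtrack and full-vector ties in the greedy both
  resolve to the alphabetically smallest label, making every output
  deterministic and the two methods comparable.
* Distance-matrix input tolerates asymmetries up to `1e-9` (averaged away);
  anything larger is rejected rather than silently symmetrized.
* The CLI prints numbers at full precision in machine-readable output;
  rounding to 4 decimals happens only in human-readable summaries.

## Synthetic data

`er_multiplex()` draws independent Erdős–Rényi layers on a shared node set
with a frozen algorithm (one uniform deviate per unordered pair, in
row-major label order, per layer in label order) so a seed pins the network
bit-for-bit across platforms. It emulates the one property the estimators
need exercised — heterogeneous reachability and degree profiles across
layers, including disconnected layers and isolated nodes at low `p` — and
none of the structure of real multiplexes (no degree heterogeneity beyond
binomial, no community structure, no inter-layer correlation). A green test
on these fixtures establishes correctness of the computations, not fidelity
of the model to any empirical system.

`example_multiplex()` is a hand-built 6-node, 4-layer family for the
directional behavior of `U` under single-link edits: adding a link that is
present in every other layer (and changes no reachability) makes the edited
layer more similar to the rest and lowers `U`; adding a link absent from
every layer, attached to a peripheral node, creates a connectivity pattern
found nowhere else and raises `U`. These directions are claims about this
constructed family, not universal theorems — on other topologies a "novel"
link can make a layer *more* similar to the rest (we observed exactly that
while designing the fixture: connecting a node that is isolated in one layer
but well-connected everywhere else *reduces* the layer's distinctiveness).

## Known limitations

* The triangle inequality is nowhere assumed for `LD`, and no algorithm in
  the package relies on it.
* Layers are unweighted and undirected; weight columns in input files are
  dropped with a warning.
* The exact solver is exponential in the number of elements (`2^K` table);
  beyond `dp_limit` only the greedy lower bound is available, and its value
  can undershoot the true `U`.
* Per-node diversity for all nodes costs `M^2` profile comparisons plus `N`
  diversity evaluations; it is quadratic in layers, not in nodes.
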