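---
title: "Counting and sampling gene family histories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and sampling gene family histories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlthist)
```

## The objects

A **species tree** here is a rooted binary tree with uniquely labeled
nodes.  Labels carry a total order, and the two children of every
internal node are stored left-to-right in increasing label order
(C-locale radix order), so an unordered tree has exactly one canonical
representation and `parse_newick(write_newick(t))` is the identity.
When a Newick string leaves internal nodes unlabeled, they are labeled
`@<smallest leaf label>_<subtree leaf count>`: two distinct subtrees
either are nested (different leaf counts) or disjoint (different
smallest leaves), so the scheme never collides — including on a
caterpillar spine, where every node shares the same smallest leaf.

A **history** is an ordered unary-binary gene tree with an event map
(`S`, `D`, `T`, `L`, `Extant`) and a species map, rooted at a single
ancestral gene in the species root.  Constraints: leaves are extant
genes or losses; binary internal nodes are speciations, duplications or
transfers; speciation children follow the species tree; duplication
children stay in their species, and the *right* child is by convention
the novel copy; a transfer keeps its original (left) copy in the donor
species and places the novel (right) copy in an incomparable species.
The **size** of a history is its number of extant genes — losses do not
count.

Losses exist only as the vanished side of a speciation.  If a
duplication or transfer could be followed immediately by a loss, any
size class would contain infinitely many histories (duplicate-and-lose
forever); restricting losses to speciations is what keeps the space
finite, and it fixes the boundary condition `H[u, 0] = 0` below.

**Ranked trees.**  A ranking orders the internal nodes (ancestors
first); it models the relative timing of speciations.  Subdividing
every edge that spans a rank yields the time-sliced unary-binary tree:
slice *i* holds the *i* lineages alive between the *i*-th and
(*i*+1)-th speciation, and slice *k* holds the extant species.  In
ranked models a transfer's receiver must be a *contemporary* — another
member of the donor's slice — which rules out the time-inconsistent
scenarios the unranked DLT model admits (and which, deliberately, it
does not forbid there: unranked DLT counts the full grammar-defined
space).

## Counting

The grammar of histories translates into per-node recurrences: with
splits `m` in `1..n-1`,

```
H[u,n] = S[u,n] + D[u,n] + T[u,n]  (+ 1 if u is a leaf and n = 1)
S[u,n] = sum_m H[ul,m] H[ur,n-m] + H[ul,n] + H[ur,n]
D[u,n] = sum_m H[u,m] H[u,n-m]
T[u,n] = sum_m H[u,m] * sum_{v incomparable with u} H[v,n-m]
```

Evaluation is a single pass over sizes (post-order within each size):
transfer terms at size `n` only consume sizes below `n`, so no fixed
point iteration is needed even though `H[u,·]` appears on both sides.
Per-node incomparable sets are computed once, and the receiver sums
`sum_v H[v, j]` are cached incrementally.

Two model-specific rules need care:

* **Unary nodes.**  In the ranked transfer models (`rDLT`, `rDTSL`)
  every lineage of a slice can duplicate or donate a transfer, so
  duplication and transfer terms apply at unary nodes too — the events
  graph below has a duplication self-loop at *every* node.  In `rDL`,
  unary nodes are pure pass-throughs (`S[u,n] = H[uc,n]` only).  This
  is a genuine modeling choice: allowing duplications at unary nodes
  would make the count depend on the ranking (a duplication on a long
  edge could sit in any of several slices), whereas with pass-throughs
  the ranking is count-neutral and `rDL = uDL` for every ranking — a
  property the test suite asserts for all shapes with up to 6 leaves.
* **Speciation-loss (`rDTSL`).**  Every binary speciation keeps exactly
  one lineage: `S[u,n] = H[ul,n] + H[ur,n]`, with the forced loss leaf
  materialized explicitly in sampled histories.

All counts are exact arbitrary-precision integers (class `bigint`,
limbs in base 1e7 stored as doubles); they overflow 2^64 already at
moderate sizes, e.g. the caterpillar with 6 leaves has ~10^78 histories
of size 50.

## Sampling

`sample_history()` is the recursive method: starting from (root, n),
pick an alternative — extant leaf, speciation split `(m, n-m)` or lost
lineage, duplication split, or transfer (receiver, split) — with
probability proportional to its count, then recurse.  This factorizes
the uniform distribution exactly along the counting recurrences.

*Numerical choice:* the choice weights are evaluated in log space from
the exact tables (top three limbs give ~1e-13 relative accuracy) rather
than with exact big-integer comparisons.  A relative weight error of
1e-13 is undetectable in any feasible goodness-of-fit experiment (the
chi-square tests here use 10^3–10^4 draws); the counts themselves stay
exact.  Splits are found by a simple cumulative scan — at the sizes
this package targets (n up to a few hundred) the boustrophedon
refinement is unnecessary.

The sampler's correctness is tested two ways: every sampled history
passes the full constraint validator, and empirical frequencies over
the exhaustively enumerated support (small trees, sizes up to 4) pass
chi-square uniformity tests at p > 0.001.  The enumeration itself is an
independent oracle whose cardinalities must equal the DP counts for
every model.

## Asymptotics in the unranked DL model

Substituting the binary-tree generating function
`B(z) = (1 − √(1 − 4z))/2` into the DL system gives
`H_u(z) = (1 − √(R_u(z)))/2` with nested radicands

```
R_u(z) = −4 + 3 √R_ul + 3 √R_ur − √(R_ul R_ur),   R_leaf(z) = 1 − 4z.
```

`R_u(0) = 1`, `R_u` is strictly decreasing, and its unique zero
`rho_u` — a simple root, strictly smaller than each child's — is the
dominant singularity of `H_u`.  The square-root singularity gives

```
h(n) = gamma * rho^(-n) * n^(-3/2) * (1 + O(1/n)),
gamma = sqrt(-rho * R'(rho)) / (4 sqrt(pi)).
```

`dominant_singularity()` brackets the zero by bisection on
`(0, min child rho)` to |R| <= 1e-14; monotonicity makes bisection
robust, and Newton steps were deliberately avoided because `R'`
degenerates as `z` approaches a child's singularity.  `gamma` uses a
central difference with step `1e-6 * rho`; its agreement with the
closed forms below (to ~1e-8) is itself a test.

**Caterpillar trees CT_k.**  Writing `X = sqrt(1 - 4z)` turns the
radicand chain into polynomials; the singularity is
`lambda_k = (1 - X_k^2)/4` where `X_k` is the minimal positive fixed
point of `s_k(X) = X`, with `s_1 = 0`,
`s_k = (3X - 4 - s_{k-1}^2)/(X - 3)` (for k = 2: `X_2 = 3 - sqrt(5)`).
The constant `alpha_k = sqrt(lambda_k * P'_k(X_k) / (8 pi X_k))` is
evaluated through the derivative recurrence of the radicand chain,
`P'_i = (3 - p_{i-1}) + (3 - X)/(2 p_{i-1}) * P'_{i-1}` with
`P'_1 = 2X` and `p_i` the already-known radicand square roots at `X_k`.

**Complete binary trees CB_h.**  Here the radicand recurrence has
z-free coefficients and iterates in closed form: `q_0 = 0`,
`q_{h+1} = (3 - sqrt(5 - q_h))^2`, `mu_h = (1 - q_h)/4`.  The same
derivative argument (`Q'_h = (3/sqrt(Q_{h-1}) - 1) Q'_{h-1}`) gives

```
beta_h = sqrt( mu_h/(4 pi) * prod_{i=1..h} (3/sqrt(q_i) - 1) ).
```

This product form is the one the package uses: it is derived directly
from the derivative recurrence and reproduces the reference values for
both families to all printed digits (growth to 2 decimals, constants to
4), including the overlap CT_2 = CB_1 to 1e-12.

For the transfer models no closed-form singularity analysis is
attempted (their functional systems are not amenable to the same
nested-radical argument); the finite-size ratio `h(n)/h(n-1)` is the
estimator, and in the uDL model — where the truth is computable — that
estimator at n = 50 is verified to sit within 5% of `1/rho` (about 3%
low, exactly as the `n^(-3/2)` correction predicts).

## The events graph and rDT-SL invariance

For ranked trees, build a directed graph on the time-sliced nodes: each
node is labeled with the set of extant leaves (numbered 1..k left to
right) its subtree reaches; speciation super-edges go to the children,
every node carries a duplication self-loop, and each slice is a
complete transfer digraph.  In the speciation-loss model a history can
be encoded by deleting its loss leaves and labeling every node with the
pair *(time slice, leftmost extant descendant leaf)* — the unique graph
node of that slice containing that leaf.  Decoding reads the event off
the traversed edge and reinserts the forced losses (the lost side of a
speciation is the child not containing the surviving lineage's leaf).
Because the encoding uses only (slice, leaf) pairs, it can be decoded
against the events graph of *any* ranked tree of the same size:
`transport_history()` is a size-preserving bijection, so the rDT-SL
count vector depends on k alone.  The package checks this at desk
scale (identical count vectors for every shape and ranking with k = 3,
4, 5 up to n = 10) and verifies the bijection by round-tripping and by
transporting full enumerated sets.

A second, independent construction (`grow_dtsl_histories()`) generates
the same set by iterative leaf expansion over the events graph,
starting from a root labeled with slice 1 and each possible tracked
leaf in turn.  The tracked leaf determines the surviving side of every
subsequent speciation, so each history arises from exactly one
expansion sequence; a root's label is recoverable from the finished
history (its leftmost extant leaf), hence enumerating all k root labels
produces each history exactly once.  Set equality with the grammar
enumeration is asserted for k = 2, 3 at small sizes.

## Random generators

* `random_topology()` draws uniformly over *distinct unordered shapes*
  (Wedderburn–Etherington counts) by the counting-based recursive
  method; the equal-split case uses a rejection step (accept unordered
  pairs; distinct ordered pairs accepted with probability 1/2) so all
  unordered pairs are equally likely.  Uniform-over-shapes is the
  natural reading of "uniform random species trees" here, since history
  counts depend only on the shape; a uniform-over-labeled-trees
  alternative would only reweight shapes without changing the per-shape
  counts being surveyed.
* `random_ranking()` draws uniformly over rankings (= linear extensions
  of the internal-node poset) by repeatedly picking an available
  subtree root with probability proportional to its internal-node
  count; the hook length formula makes this exactly uniform, and the
  tests check it against an independent hook-length oracle.

Both take a single integer seed and are fully deterministic given it.

## What the tests do and do not show

Test inputs are canonical families (caterpillar, complete binary,
balanced), exhaustive shape enumerations up to k = 6, and uniform
random shapes.  These cover the combinatorial claims exactly — counts,
bijections and asymptotics are mathematical statements about the model,
not estimates — but histories here are *unweighted*: real gene families
evolve under rate models in which duplications, transfers and losses
are far rarer than uniform sampling over histories suggests.  Uniform
histories describe the geometry of the search space (e.g. typical
scores are high, and adding transfers both enlarges the space and
lowers typical scores), not the posterior of any rate-based model.
Problem sizes in the shipped experiments are deliberately modest — one
random 16-leaf tree, histories of size 30, 10^3 samples per model in
the score comparison; surveys over hundreds of large trees follow the
same code paths and only cost more time.

## Known limitations

* Histories are *ordered* (the novel copy of a duplication is
  distinguishable), which matches an evolutionary reading but differs
  from classical reconciliations; reconciliation counting is out of
  scope.
* Counting is parameterized by history size only, not by the
  distribution of genes across extant species.
* Closed-form asymptotics cover the unranked DL model; for the
  transfer models only the finite-size ratio estimator is provided.
* `enumerate_histories()` and `grow_dtsl_histories()` are oracles for
  tests, hard-capped at tiny sizes.
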