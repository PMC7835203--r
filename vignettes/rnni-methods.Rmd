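---
title: "Ranked NNI tree space and the FindPath algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranked NNI tree space and the FindPath algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnni)
```

## The objects

A *ranked phylogenetic tree* on leaves $\{a_1,\dots,a_n\}$ is a rooted
binary tree whose $n-1$ internal nodes are bijectively ranked
$1,\dots,n-1$ with every child ranked strictly below its parent; leaves
have rank 0. Ranks model the temporal order of evolutionary events
(divergences, transmissions, metastatic seedings), which is exactly the
information that unranked topology-only metrics discard. A ranked tree
is identified by its **cluster representation**: the list of leaf sets
descending from the internal nodes, in rank order. This representation
is unique, which is why `rnni` stores trees canonically as sorted
cluster sequences — equality, hashing and serialisation all reduce to
string comparison of `format_clusters()` output.

There are $(n-1)!\,n!/2^{n-1}$ ranked trees on $n$ leaves. The package
verifies this constructively: `enumerate_trees()` recurses over *merge
sequences* (at each rank, merge one unordered pair of current partition
blocks), and merge sequences are in bijection with ranked trees —
$\prod_{k=2}^{n}\binom{k}{2}$ equals the closed-form count. The same
bijection makes `random_tree()` an *exactly* uniform sampler: drawing a
uniform block pair at every rank draws a uniform merge sequence.

## The graph

`RNNI(ρ)` has one vertex per ranked tree. Moves act on an *interval*,
a pair of nodes with consecutive ranks $t, t+1$:

* **rank move** (weight $\rho \ge 0$): swap the two ranks, allowed only
  when the nodes are not adjacent in the tree;
* **NNI move** (weight 1): on an *edge interval*, exchange one child
  subtree of the lower node with the upper node's other child subtree.

The NNI move is classically defined by contracting the edge and
re-expanding it in the two other ways. We implement the equivalent
constructive form (swap a child block of the lower node with the upper
node's spare block) because it is deterministic, cheap to canonicalise,
and reproduces every intermediate tree printed in worked examples. A
move is recorded as its interval rank plus, for NNI, the `swap_block`
leaf set — meaningful without reference to any in-memory tree, which is
what makes serialised move lists replayable.

Each tree has between $n-2$ and $2(n-2)$ neighbours (one rank move per
non-edge interval, two NNI moves per edge interval). `neighbourhood()`
reports distinct moves separately and never merges coincidentally equal
results; in the exhaustively checked spaces ($n \le 5$) no two distinct
moves ever produced the same neighbour (`rnni_graph()$dup_moves`
records this).

## FindPath

`findpath(T, R)` scans the destination's clusters $C_1,\dots,C_{n-2}$
in rank order. While the most recent common ancestor of $C_k$ in the
working tree sits at rank $r > k$, the unique move on the interval
$[r-1, r]$ lowering it is applied: the rank swap if the interval is not
an edge, otherwise the single NNI move that swaps out the child subtree
of the rank-$(r-1)$ node disjoint from $C_k$. Uniqueness holds because
by the time $C_k$ is processed its two constituent blocks are complete
subtrees of the working tree rooted below rank $k$, so exactly one
child of the lower node meets $C_k$; the implementation asserts this
rather than tie-breaking. After iteration $k$ the first $k$ clusters of
the working tree equal $R$'s, so the procedure terminates at $R$.

The resulting path is a shortest path in the unit-weight graph
`RNNI(1)`; the package certifies this exhaustively at desk scale by
comparing `findpath_distance()` with breadth-first-search distances over
*all* ordered pairs on 4 and 5 leaves (306 and 32,220 pairs). Reversed
caterpillar pairs attain the worst case $\binom{n-1}{2}$, which is why
no sub-quadratic algorithm can exist for move-list output.

For $\rho \neq 1$ FindPath is provably not optimal:
`shortest_path_gap()` reproduces the two canonical 4-leaf
counterexamples — a weight-$(2+\rho)$ FindPath path beaten by an
all-NNI weight-3 path when $\rho > 1$, and a weight-3 all-NNI FindPath
path beaten by a rank-plus-two-NNI weight-$(2+\rho)$ path when
$\rho < 1$. `findpath_weight()` is therefore documented, and should be
read, as an *upper bound* on the `RNNI(ρ)` distance, tight at
$\rho = 1$.

### Complexity and representation choices

The core runs in $O(n^2)$: one $O(n)$ ancestor search per destination
cluster, then $O(1)$ per move, implemented in C++ over parent/child
arrays with a rank-to-node index. The path object stores the *move
list*; materialising trees via `path_trees()` costs an extra factor of
$n$ and is deliberately opt-in, keeping the distance computation's
output size quadratic. Large-instance path validity is checked by an
independent C++ interpreter that replays the compact move list (interval
rank, move kind, which child — by smallest descendant leaf — is swapped
out) and must land exactly on the destination.

## The exact oracle

`rnni_graph()` materialises the whole tree space (capped at $n = 7$,
56,700 vertices, because the count is super-exponential) with one
weighted edge per move, and delegates shortest paths, all-pairs
distances and diameters to `igraph` (Dijkstra for weighted $\rho$, BFS
at $\rho = 1$). It is the package's ground truth: optimality of
FindPath, metric axioms, degree bounds, connectivity and the
counterexample gaps are all asserted against it. Weighted equality
assertions use an absolute tolerance of $10^{-9}$; distances themselves
are sums of exactly representable weights, so no looser tolerance is
needed.

The diameter is reported only for $\rho = 1$ graphs: the quadratic
worst-case bound concerns the unweighted graph, and exact small-$n$
diameters are computed rather than relying on any closed form.

## Randomised test conditions

The suite's randomised checks emulate the regime a practitioner meets:
uniformly sampled ranked trees (the sampler above) at $n = 10$ for
metric-axiom spot checks (100 triples), $n = 12$ shared-cluster pairs
for cluster preservation (100 pairs), 200 random pairs at $n = 30$ for
move-list replay, and a single $n = 2000$ pair for the quadratic-time
scalability check; exhaustive certification covers $n \le 5$ and
degree bounds up to $n = 6$. Uniform sampling exercises tree *shape*
and *rank* variation fully, but real posterior samples are correlated
and clustered; passing tests therefore certify the algorithm and data
structures, not statistical behaviour on any particular inference
output. Shared-cluster pairs are built by stacking independent random
subtrees on a fixed leaf subset below independent random outer trees,
which guarantees the shared cluster without constraining the rest of
the topology.

## Interchange conventions

The cluster-string grammar is fixed as
`'[' '{' label (',' label)* '}' (',' ...)* ']'` with labels over
`[A-Za-z0-9_]` and insignificant whitespace; subscripted labels are
flattened (`a1`). For Newick interchange, ranked trees carry no branch
lengths of their own, so `write_newick()` places the rank-$t$ node at
time $t$ (unit spacing) and `read_newick()` inverts this for any
ultrametric input: node times are recovered from depths, leaves must
sit within `epsilon` (default $10^{-6}$, matching common tree-file
print precision) of time 0, and internal times must be strictly
separated by more than `epsilon`. Tied times are an error by default —
silently ordering them would fabricate rank data; `tie_policy = "lex"`
opts into deterministic resolution by smallest descendant label, and
ties that no ranking can satisfy (parent and child at equal times)
remain errors. $n = 2$ is admitted (one internal node, no moves);
$n = 1$ is rejected as rankless.

## Known limitations

* Shortest paths and distances are exact only at $\rho = 1$; for
  $\rho \neq 1$ the package offers the FindPath upper bound and, for
  $n \le 7$, the exact oracle. No polynomial algorithm for general
  $\rho$ is attempted (at $\rho = 0$ the problem is NP-hard).
* Unranked, non-binary, unrooted and branch-length-valued trees are out
  of scope; SPR/TBR-type rearrangements are not implemented.
* Enumeration and the explicit graph are desk-scale tools by design;
  at $n = 7$ graph construction takes minutes in R.
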