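# rnni

Shortest-path distances between **ranked phylogenetic trees** under the
ranked nearest neighbour interchange (RNNI) operation.

## Why ranked trees

In many applications — epidemic transmission chains, cancer clone
phylogenies, species divergence dating — the *order in time* of the
internal nodes of a phylogeny carries as much information as the
branching structure itself. A ranked tree equips a rooted binary tree on
leaves `a1..an` with a bijective ranking `1..n-1` of its internal nodes
(children ranked below parents), and is uniquely described by its
*cluster representation*, e.g.

```
[{a1,a2},{a1,a2,a3},{a4,a5},{a1,a2,a3,a4,a5}]
```

The RNNI graph connects two ranked trees when one arises from the other
by a single move on an interval of consecutive ranks `t, t+1`:

* a **rank move** (weight `ρ ≥ 0`) swaps the two ranks when the nodes
  are not adjacent, changing event order but not topology;
* an **NNI move** (weight 1) rearranges an edge interval, exchanging a
  child subtree of the lower node with the upper node's other child.

The distance `d(T, R)` is the minimal total weight of a move sequence.
Classical rearrangement distances (NNI, SPR, TBR) are NP-hard; the
central result implemented here is that in the unit-weight graph
`RNNI(1)` the **FindPath** algorithm constructs a provably shortest path
in `O(n²)` time — scanning the destination's clusters `C_1..C_{n-2}` in
rank order and repeatedly applying the *unique* move that pulls the most
recent common ancestor of `C_k` down one rank until it sits at rank `k`.
Worst-case length `(n-1)(n-2)/2` is attained by reversed caterpillar
pairs, so the algorithm is rate-optimal. Shortest paths additionally
preserve any cluster the two trees share — a biologically meaningful
property that plain NNI lacks. For `ρ ≠ 1` FindPath is only an upper
bound (and at `ρ = 0` the problem is NP-hard); the package ships an
exact brute-force oracle over the full tree space for small `n` that
certifies both facts.

## Worked example

The 4-leaf pair whose FindPath route mixes both move kinds:

```r
library(rnni)
T <- parse_clusters("[{a1,a2},{a1,a2,a3},{a1,a2,a3,a4}]")
R <- parse_clusters("[{a3,a4},{a2,a3,a4},{a1,a2,a3,a4}]")
p <- findpath(T, R)
p
#> <rnni_path> 3 moves (2 NNI, 1 rank)
#>   2 nni {a1,a2}
#>   1 rank
#>   2 nni {a1}
findpath_distance(T, R)
#> [1] 3
```

Three moves: an NNI on interval 2 swapping out `{a1,a2}`, a rank swap on
interval 1, and an NNI on interval 2 swapping out the leaf `a1` — so
`d(T, R) = 3` in `RNNI(1)`. Under a rank-move weight `ρ = 2` the same
move list costs `2 + ρ = 4`, and the exact oracle shows it is then no
longer optimal (an all-NNI detour of weight 3 exists):

```r
shortest_path_gap(T, R, rho = 2)
#> $findpath
#> [1] 4
#> $oracle
#> [1] 3
#> $gap
#> [1] 1
```

Other entry points: `path_trees()` materialises every tree along a path;
`enumerate_trees()` / `random_tree()` enumerate or uniformly sample the
`(n-1)! n! / 2^(n-1)` ranked trees; `rnni_graph()`, `oracle_distance()`,
`graph_diameter()` expose the explicit graph (e.g. the 5-leaf diameter
is 6); `read_newick()` / `write_newick()` convert ultrametric Newick to
ranks and back. A command-line tool is installed as `exec/rnni`:

```sh
Rscript exec/rnni distance "[{a1,a2},{a1,a2,a3}]" "[{a2,a3},{a1,a2,a3}]"
```

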