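# shared fixtures: all built in code, nothing on disk

fig1_tree <- function() {
  parse_clusters("[{a1,a2},{a1,a2,a3},{a4,a5},{a1,a2,a3,a4,a5}]")
}

# 4-leaf counterexample pair where FindPath uses two NNI moves with a rank
# move in between (weight 2 + rho); a 3-NNI detour beats it for rho > 1
gap_pair_rank <- function() {
  list(T = parse_clusters("[{a1,a2},{a1,a2,a3},{a1,a2,a3,a4}]"),
       R = parse_clusters("[{a3,a4},{a2,a3,a4},{a1,a2,a3,a4}]"))
}

# 4-leaf pair where FindPath uses three NNI moves (weight 3); a
# rank-plus-two-NNI detour beats it for rho < 1
gap_pair_nni <- function() {
  list(T = parse_clusters("[{a1,a2},{a3,a4},{a1,a2,a3,a4}]"),
       R = parse_clusters("[{a1,a3},{a1,a3,a4},{a1,a2,a3,a4}]"))
}

# memoised enumerations and oracle graphs (cheap to rebuild, but reused a lot)
.fixture_cache <- new.env(parent = emptyenv())

enum_trees <- function(n) {
  key <- paste0("enum", n)
  if (!exists(key, envir = .fixture_cache))
    assign(key, enumerate_trees(n), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

oracle_graph <- function(n, rho = 1) {
  key <- paste0("graph", n, "_", rho)
  if (!exists(key, envir = .fixture_cache))
    assign(key, rnni_graph(n, rho = rho), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# pair of random ranked trees on a1..an sharing the cluster a1..am: each
# tree stacks a random ranked subtree on the shared leaves below a random
# ranked tree on the remaining blocks
shared_cluster_pair <- function(n, m, seed) {
  stopifnot(m >= 2, n > m)
  X <- paste0("a", seq_len(m))
  rest <- paste0("a", (m + 1):n)
  build <- function(s) {
    sub <- random_tree(X, seed = s)
    outer <- random_tree(c("ZZblock", rest), seed = s + 1L)
    expand <- function(cl) {
      if ("ZZblock" %in% cl) sort(c(setdiff(cl, "ZZblock"), X)) else cl
    }
    ranked_tree(c(sub$clusters, lapply(outer$clusters, expand)))
  }
  list(T = build(seed), R = build(seed + 1000L), shared = X)
}

# does every tree along the FindPath path contain the cluster X?
path_preserves_cluster <- function(T, R, X) {
  trees <- path_trees(findpath(T, R))
  X <- sort(X)
  all(vapply(trees, function(tr)
    any(vapply(tr$clusters, identical, logical(1), y = X)), logical(1)))
}
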