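#' Explicit RNNI(rho) graph for small leaf counts
#'
#' Builds the full rearrangement graph on *all* ranked trees over a
#' label set: one vertex per tree (canonical cluster-string key), one
#' edge per RNNI move, weighted 1 for NNI moves and `rho` for rank
#' moves.  This is the ground-truth object against which the FindPath
#' algorithm can be certified at desk scale; the vertex count
#' `(n-1)! n! / 2^(n-1)` grows super-exponentially, so construction is
#' capped at `n = 7` (56,700 trees).
#'
#' @param labels character label vector or a single integer `n`.
#' @param rho non-negative rank-move weight.
#' @return An object of class `rnni_graph`: list with the `igraph`
#'   object (`graph`), the `trees`, their canonical `keys`, `rho`, `n`,
#'   and `dup_moves`, the number of move pairs that produced an already
#'   recorded adjacency (0 expected: distinct moves give distinct
#'   neighbours).
#' @examples
#' G <- rnni_graph(4)
#' igraph::vcount(G$graph)  # 18
#' @export
rnni_graph <- function(labels, rho = 1) {
  rho <- check_rho(rho)
  labels <- default_labels(labels)
  if (length(labels) > 7L)
    rnni_abort("explicit graph construction capped at n = 7", "cap")
  trees <- enumerate_trees(labels)
  keys <- vapply(trees, format_clusters, character(1))
  index <- seq_along(keys)
  names(index) <- keys
  nmax <- length(trees) * 2L * max(length(labels) - 2L, 1L)
  from <- integer(nmax); to <- integer(nmax); wt <- numeric(nmax)
  ne <- 0L
  seen <- new.env(hash = TRUE, parent = emptyenv())
  dup <- 0L
  for (i in seq_along(trees)) {
    if (trees[[i]]$n < 3L) break  # n = 2: single vertex, no moves
    js <- integer(0)
    for (nb in neighbourhood(trees[[i]], rho = rho)) {
      j <- index[[format_clusters(nb$tree)]]
      if (j %in% js) dup <- dup + 1L  # two distinct moves, same result
      js <- c(js, j)
      key <- paste0(min(i, j), "-", max(i, j))
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        ne <- ne + 1L
        from[ne] <- min(i, j); to[ne] <- max(i, j); wt[ne] <- nb$weight
      }
    }
  }
  from <- from[seq_len(ne)]; to <- to[seq_len(ne)]; wt <- wt[seq_len(ne)]
  g <- igraph::make_empty_graph(n = length(trees), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = keys)
  if (length(from) > 0L)
    g <- igraph::add_edges(g, rbind(from, to), weight = wt)
  structure(
    list(graph = g, trees = trees, keys = keys, rho = rho,
         n = length(labels), dup_moves = dup),
    class = "rnni_graph"
  )
}

#' @export
print.rnni_graph <- function(x, ...) {
  cat("<rnni_graph> n = ", x$n, ", rho = ", x$rho, ": ",
      length(x$trees), " trees, ", igraph::ecount(x$graph), " moves\n",
      sep = "")
  invisible(x)
}

graph_vertex <- function(G, tree) {
  key <- format_clusters(tree)
  i <- match(key, G$keys)
  if (is.na(i))
    rnni_abort("tree is not a vertex of this graph (label set mismatch?)",
               "vertex")
  i
}

#' Exact shortest-path weight in the explicit graph
#'
#' Weighted shortest-path (uniform-cost) distance between two trees in a
#' graph built by [rnni_graph()].  At `rho = 1` this is the exact RNNI
#' distance and serves as the brute-force reference for
#' [findpath_distance()].
#'
#' @param G an `rnni_graph`.
#' @param T,R `ranked_tree` vertices of `G`.
#' @return numeric distance.
#' @export
oracle_distance <- function(G, T, R) {
  stopifnot(inherits(G, "rnni_graph"))
  i <- graph_vertex(G, T); j <- graph_vertex(G, R)
  as.numeric(igraph::distances(
    G$graph, v = i, to = j,
    weights = igraph::E(G$graph)$weight, algorithm = "dijkstra"))
}

#' All-pairs shortest-path matrix of an explicit RNNI graph
#'
#' @param G an `rnni_graph`.
#' @return symmetric numeric matrix of exact distances, rows/columns in
#'   the order of `G$trees`.
#' @export
oracle_all_distances <- function(G) {
  stopifnot(inherits(G, "rnni_graph"))
  w <- if (G$rho == 1) NA else igraph::E(G$graph)$weight
  igraph::distances(G$graph, weights = w)
}

#' Diameter of the unit-weight RNNI graph
#'
#' Maximum over all tree pairs of the breadth-first-search distance.
#' Only defined here for `rho = 1` graphs: the quadratic worst-case path
#' bound concerns the unweighted graph, and a weighted diameter would be
#' a different quantity.
#'
#' @param G an `rnni_graph` built with `rho = 1`.
#' @return numeric diameter.
#' @export
graph_diameter <- function(G) {
  stopifnot(inherits(G, "rnni_graph"))
  if (G$rho != 1)
    rnni_abort("diameter is only reported for the rho = 1 graph", "rho")
  as.numeric(igraph::diameter(G$graph, weights = NA))
}

#' FindPath weight versus the exact RNNI(rho) distance
#'
#' Computes both the weight of the (rho-independent) FindPath move list
#' and the exact shortest-path weight in the explicit graph, for trees
#' small enough to enumerate.  The gap `findpath - oracle` is always
#' `>= 0`; it is guaranteed to vanish at `rho = 1`, and there are tree
#' pairs with a strictly positive gap for every `rho != 1`.
#'
#' @param T,R `ranked_tree` objects on a shared label set (n <= 7).
#' @param rho non-negative rank-move weight.
#' @param G optional pre-built `rnni_graph` on the same labels and rho.
#' @return `list(findpath, oracle, gap)`.
#' @examples
#' T <- parse_clusters("[{a1,a2},{a1,a2,a3},{a1,a2,a3,a4}]")
#' R <- parse_clusters("[{a3,a4},{a2,a3,a4},{a1,a2,a3,a4}]")
#' shortest_path_gap(T, R, rho = 2)  # findpath 4, oracle 3
#' @export
shortest_path_gap <- function(T, R, rho = 1, G = NULL) {
  rho <- check_rho(rho)
  check_same_labels(T, R)
  if (is.null(G)) G <- rnni_graph(T$labels, rho = rho)
  if (G$rho != rho || !identical(sort(G$trees[[1L]]$labels), T$labels))
    rnni_abort("supplied graph does not match the trees' labels and rho",
               "vertex")
  fp <- findpath_weight(T, R, rho = rho)
  oc <- oracle_distance(G, T, R)
  list(findpath = fp, oracle = oc, gap = fp - oc)
}
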