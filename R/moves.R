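#' @title RNNI moves on ranked trees
#'
#' @description The RNNI(rho) graph has one vertex per ranked tree and
#' two kinds of edges, both acting on an *interval* -- a pair of internal
#' nodes with consecutive ranks `t`, `t + 1`:
#'
#' * a **rank move** (weight `rho >= 0`) swaps the ranks of the two
#'   nodes, allowed only when they are not connected by an edge;
#' * an **NNI move** (weight 1) acts on an *edge interval* (lower node a
#'   child of the upper) and exchanges one child subtree of the lower
#'   node with the upper node's other child subtree; the two possible
#'   results and the original tree all contract to the same degree-four
#'   tree.
#'
#' A move is addressed by the lower rank `t` of its interval; an NNI move
#' additionally records `swap_block`, the leaf set of the child subtree
#' of the rank-`t` node that is exchanged, which pins down which of the
#' two NNI results is meant independently of any in-memory tree.
#'
#' @param kind `"rank"` or `"nni"`.
#' @param t integer rank of the lower node of the interval.
#' @param swap_block for NNI moves, character vector of leaf labels.
#' @return `rnni_move()` returns an object of class `rnni_move`.
#' @export
rnni_move <- function(kind, t, swap_block = NULL) {
  kind <- match.arg(kind, c("rank", "nni"))
  if (kind == "rank" && !is.null(swap_block))
    rnni_abort("rank moves carry no swap_block", "move")
  if (kind == "nni") {
    if (is.null(swap_block) || length(swap_block) == 0L)
      rnni_abort("NNI moves need a non-empty swap_block", "move")
    swap_block <- sort(unique(as.character(swap_block)))
  }
  structure(list(kind = kind, t = as.integer(t), swap_block = swap_block),
            class = "rnni_move")
}

#' @export
print.rnni_move <- function(x, ...) {
  cat(format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.rnni_move <- function(x, ...) {
  if (x$kind == "rank") paste(x$t, "rank")
  else paste(x$t, "nni",
             paste0("{", paste(x$swap_block, collapse = ","), "}"))
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0)
    rnni_abort("`rho` must be a single non-negative number", "rho")
  as.numeric(rho)
}

# leaf set below node id (leaf i = i, internal rank t = n + t)
cluster_of_id <- function(tree, id) {
  if (id <= tree$n) tree$labels[id] else tree$clusters[[id - tree$n]]
}

#' Is an interval an edge interval?
#'
#' The interval between the nodes of ranks `t` and `t + 1` is an *edge
#' interval* iff the lower node is a child of the upper, equivalently iff
#' the rank-`t` cluster is contained in the rank-`t+1` cluster.
#'
#' @param tree a `ranked_tree`.
#' @param t integer rank, `1 <= t <= n - 2`.
#' @return logical.
#' @export
is_edge_interval <- function(tree, t) {
  stopifnot(inherits(tree, "ranked_tree"))
  t <- as.integer(t)
  if (length(t) != 1L || is.na(t) || t < 1L || t > tree$n - 2L)
    rnni_abort(sprintf("interval rank must lie in 1..%d", tree$n - 2L),
               "rank")
  (tree$n + t) %in% tree$merge[t + 1L, ]
}

#' Apply a rank move
#'
#' Swaps the ranks of the nodes of ranks `t` and `t + 1`; defined only
#' when the interval is not an edge (swapping the ranks of a parent and
#' its child would violate the ranking).  There is exactly one rank move
#' per non-edge interval, and it is an involution.
#'
#' @inheritParams is_edge_interval
#' @return a `ranked_tree`.
#' @export
apply_rank_move <- function(tree, t) {
  if (is_edge_interval(tree, t))
    rnni_abort(sprintf(
      "interval [%d, %d] is an edge; a rank move is undefined", t, t + 1L),
      "move")
  cl <- tree$clusters
  cl[c(t, t + 1L)] <- cl[c(t + 1L, t)]
  ranked_tree(cl, tree$labels)
}

#' The two NNI neighbours on an edge interval
#'
#' With `A`, `B` the child clusters of the rank-`t` node and `C` the
#' other child cluster of the rank-`t+1` node (any of which may be a
#' single leaf), the two neighbours replace the rank-`t` cluster by
#' `A + C` (exchanging `B` with `C`) and by `B + C` (exchanging `A` with
#' `C`); all other clusters are unchanged.  Together with the input these
#' are the three trees sharing the same contracted degree-four tree.
#'
#' @inheritParams is_edge_interval
#' @return list of two elements, each `list(move, tree)` where `move` is
#'   the `rnni_move` taking the input to `tree`.
#' @export
nni_neighbours <- function(tree, t) {
  if (!is_edge_interval(tree, t))
    rnni_abort(sprintf(
      "interval [%d, %d] is not an edge; NNI moves are undefined",
      t, t + 1L), "move")
  n <- tree$n
  A <- cluster_of_id(tree, tree$merge[t, 1L])
  B <- cluster_of_id(tree, tree$merge[t, 2L])
  other <- setdiff(tree$merge[t + 1L, ], n + t)
  C <- cluster_of_id(tree, other)
  mk <- function(new_low, swapped) {
    cl <- tree$clusters
    cl[[t]] <- sort(new_low)
    list(move = rnni_move("nni", t, swap_block = swapped),
         tree = ranked_tree(cl, tree$labels))
  }
  list(mk(c(A, C), B), mk(c(B, C), A))
}

#' Apply an RNNI move to a tree
#'
#' @param tree a `ranked_tree`.
#' @param move an `rnni_move`.
#' @return the neighbouring `ranked_tree`.
#' @export
apply_move <- function(tree, move) {
  stopifnot(inherits(tree, "ranked_tree"), inherits(move, "rnni_move"))
  if (move$kind == "rank") return(apply_rank_move(tree, move$t))
  t <- move$t
  if (!is_edge_interval(tree, t))
    rnni_abort(sprintf(
      "interval [%d, %d] is not an edge; cannot apply NNI", t, t + 1L),
      "move")
  A <- cluster_of_id(tree, tree$merge[t, 1L])
  B <- cluster_of_id(tree, tree$merge[t, 2L])
  keep <- if (identical(move$swap_block, A)) B
          else if (identical(move$swap_block, B)) A
          else rnni_abort(
            "swap_block is not a child cluster of the rank-t node", "move")
  other <- setdiff(tree$merge[t + 1L, ], tree$n + t)
  C <- cluster_of_id(tree, other)
  cl <- tree$clusters
  cl[[t]] <- sort(c(keep, C))
  ranked_tree(cl, tree$labels)
}

#' The full RNNI neighbourhood of a tree
#'
#' Iterates over intervals `t = 1..n-2`: each edge interval contributes
#' its two NNI neighbours (weight 1), each non-edge interval its single
#' rank neighbour (weight `rho`).  The degree of every tree therefore
#' lies between `n - 2` and `2(n - 2)`.  Distinct moves are reported
#' separately even if they happened to produce equal trees.
#'
#' @param tree a `ranked_tree` with `n >= 3`.
#' @param rho non-negative rank-move weight (default 1).
#' @return list of `list(move, tree, weight)`.
#' @export
neighbourhood <- function(tree, rho = 1) {
  stopifnot(inherits(tree, "ranked_tree"))
  rho <- check_rho(rho)
  if (tree$n < 3L)
    rnni_abort("a tree on 2 leaves has no intervals, hence no moves",
               "move")
  out <- list()
  for (t in seq_len(tree$n - 2L)) {
    if (is_edge_interval(tree, t)) {
      for (nb in nni_neighbours(tree, t))
        out[[length(out) + 1L]] <-
          list(move = nb$move, tree = nb$tree, weight = 1)
    } else {
      out[[length(out) + 1L]] <-
        list(move = rnni_move("rank", t),
             tree = apply_rank_move(tree, t), weight = rho)
    }
  }
  out
}

#' Weight of a move sequence
#'
#' Sums the weights of the moves of a path: 1 per NNI move, `rho` per
#' rank move.  At `rho = 1` this is simply the move count.
#'
#' @param moves list of `rnni_move` objects (or an `rnni_path`).
#' @param rho non-negative rank-move weight.
#' @return numeric path weight.
#' @export
path_weight <- function(moves, rho = 1) {
  rho <- check_rho(rho)
  if (inherits(moves, "rnni_path")) moves <- moves$moves
  if (length(moves) == 0L) return(0)
  kinds <- vapply(moves, function(m) m$kind, character(1))
  sum(kinds == "nni") + rho * sum(kinds == "rank")
}
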