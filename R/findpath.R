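#' Shortest RNNI paths between ranked trees (FindPath)
#'
#' `findpath()` runs the FindPath algorithm from tree `T` to tree `R` on
#' a shared label set.  The destination's clusters are visited in rank
#' order `k = 1..n-2`; while the most recent common ancestor of cluster
#' `C_k` in the working tree sits above rank `k`, the unique RNNI move
#' that lowers it by one rank is applied (a rank swap on a non-edge
#' interval, otherwise the one NNI move that shrinks the ancestor's
#' cluster).  After iteration `k` the first `k` clusters of the working
#' tree equal those of `R`.  The resulting path is a shortest path in the
#' unit-weight graph RNNI(1), its length never exceeds
#' `(n-1)(n-2)/2`, and every cluster shared by `T` and `R` is present in
#' every tree along it.
#'
#' The path is returned as a move list (quadratic output size); the
#' intermediate trees can be materialised with [path_trees()], which
#' costs an extra factor of `n`.
#'
#' @param T,R `ranked_tree` objects on the same label set.
#' @return An object of class `rnni_path`: a list with the `start` and
#'   `end` trees, `moves` (list of [rnni_move()]), and the move-kind
#'   counts `n_nni`, `n_rank`.
#' @seealso [findpath_distance()] for the move count alone (no move list
#'   is materialised), [findpath_weight()] for the path's weight under a
#'   rank-move weight `rho`.
#' @examples
#' T <- parse_clusters("[{a1,a2},{a3,a4},{a1,a2,a3,a4}]")
#' R <- parse_clusters("[{a1,a3},{a1,a3,a4},{a1,a2,a3,a4}]")
#' p <- findpath(T, R)
#' p$moves
#' path_trees(p)
#' @export
findpath <- function(T, R) {
  check_same_labels(T, R)
  res <- .fp_core(T$merge, R$merge, 2L)
  m <- length(res$t)
  moves <- vector("list", m)
  for (i in seq_len(m)) {
    moves[[i]] <- if (res$kind[i] == 0L) {
      rnni_move("rank", res$t[i])
    } else {
      rnni_move("nni", res$t[i], swap_block = T$labels[res$swap[[i]]])
    }
  }
  structure(
    list(start = T, end = R, moves = moves,
         n_nni = res$n_nni, n_rank = res$n_rank),
    class = "rnni_path"
  )
}

#' @export
print.rnni_path <- function(x, ...) {
  cat("<rnni_path> ", length(x$moves), " moves (",
      x$n_nni, " NNI, ", x$n_rank, " rank)\n", sep = "")
  for (m in x$moves) cat("  ", format(m), "\n", sep = "")
  invisible(x)
}

#' Materialise the trees along an RNNI path
#'
#' Replays the move list of a path, returning every tree visited
#' (including the endpoints).  Writing each tree out is linear in `n`,
#' so this costs a factor of `n` more than the move list itself.
#'
#' @param path an `rnni_path`.
#' @return list of `ranked_tree` objects, length `length(path$moves) + 1`.
#' @export
path_trees <- function(path) {
  stopifnot(inherits(path, "rnni_path"))
  out <- vector("list", length(path$moves) + 1L)
  out[[1L]] <- path$start
  for (i in seq_along(path$moves))
    out[[i + 1L]] <- apply_move(out[[i]], path$moves[[i]])
  out
}

#' RNNI distance between two ranked trees
#'
#' Length of the FindPath move list, computed in `O(n^2)` without
#' materialising any intermediate tree.  This equals the shortest-path
#' distance `d(T, R)` in the unit-weight graph RNNI(1); it is symmetric
#' even though the path construction itself is directed.
#'
#' @inheritParams findpath
#' @return non-negative number of moves.
#' @examples
#' T <- caterpillar_tree(paste0("a", 1:6))
#' R <- caterpillar_tree(paste0("a", c(1, 6:2)))
#' findpath_distance(T, R)  # (6-1)(6-2)/2 = 10
#' @export
findpath_distance <- function(T, R) {
  check_same_labels(T, R)
  res <- .fp_core(T$merge, R$merge, 0L)
  res$n_nni + res$n_rank
}

#' Weight of the FindPath path under a rank-move weight rho
#'
#' The FindPath move list does not depend on `rho`; this reports its
#' weight with NNI moves weighing 1 and rank moves weighing `rho`.  The
#' value is an **upper bound** on the RNNI(rho) distance: it is tight at
#' `rho = 1` and provably not tight for some tree pairs whenever
#' `rho != 1` (see [shortest_path_gap()]).
#'
#' @inheritParams findpath
#' @param rho non-negative rank-move weight.
#' @return numeric path weight.
#' @export
findpath_weight <- function(T, R, rho = 1) {
  rho <- check_rho(rho)
  check_same_labels(T, R)
  res <- .fp_core(T$merge, R$merge, 0L)
  res$n_nni + rho * res$n_rank
}

#' One FindPath step
#'
#' Given a working tree in which the most recent common ancestor of a
#' destination cluster `C` sits at rank `r > k`, returns the unique RNNI
#' move on the interval between ranks `r - 1` and `r` that lowers the
#' ancestor to rank `r - 1`: the rank swap when the interval is not an
#' edge, otherwise the NNI move that exchanges the child subtree of the
#' rank-`(r-1)` node disjoint from `C` with the rank-`r` node's other
#' child subtree.  Callers must ensure the constituent blocks of `C` are
#' already complete subtrees of `T1` (FindPath's visiting order
#' guarantees this); the step errors if that fails to hold.
#'
#' @param T1 a `ranked_tree` (the working tree).
#' @param C character vector, a cluster of the destination tree.
#' @param k integer target rank for `C`.
#' @return `list(move, tree)`: the move and the tree it produces.
#' @export
findpath_step <- function(T1, C, k) {
  stopifnot(inherits(T1, "ranked_tree"))
  C <- sort(unique(as.character(C)))
  r <- mrca_rank(T1, C)
  if (r <= k)
    rnni_abort(sprintf(
      "mrca of C already has rank %d <= target %d: no step needed", r, k),
      "step")
  if (!is_edge_interval(T1, r - 1L)) {
    mv <- rnni_move("rank", r - 1L)
    return(list(move = mv, tree = apply_move(T1, mv)))
  }
  # edge interval: the child of the rank-(r-1) node disjoint from C is
  # swapped out; exactly one child of the lower node may meet C
  A <- cluster_of_id(T1, T1$merge[r - 1L, 1L])
  B <- cluster_of_id(T1, T1$merge[r - 1L, 2L])
  hitA <- length(intersect(A, C)) > 0L
  hitB <- length(intersect(B, C)) > 0L
  if (hitA == hitB)
    rnni_abort(
      "C is not reachable by a unique NNI step; its blocks are not complete subtrees of the working tree",
      "step")
  mv <- rnni_move("nni", r - 1L, swap_block = if (hitA) B else A)
  list(move = mv, tree = apply_move(T1, mv))
}

check_same_labels <- function(T, R) {
  stopifnot(inherits(T, "ranked_tree"), inherits(R, "ranked_tree"))
  if (!identical(T$labels, R$labels))
    rnni_abort("trees are on different label sets", "labels")
  invisible(TRUE)
}

# internal: run FindPath with compact move recording and replay the move
# list through an independent interpreter; TRUE iff the replay ends at R
fp_replay_ok <- function(T, R) {
  check_same_labels(T, R)
  res <- .fp_core(T$merge, R$merge, 1L)
  final <- .fp_replay(T$merge, res$t, res$kind, res$which)
  identical(final, R$merge)
}
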