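#' Ranked phylogenetic trees
#'
#' A ranked phylogenetic tree is a rooted binary tree on `n` uniquely
#' labelled leaves whose `n - 1` internal nodes are bijectively ranked
#' `1..n-1` such that every child has a strictly smaller rank than its
#' parent (leaves have rank 0).  The tree is stored canonically as its
#' *cluster representation*: the list of leaf sets descending from each
#' internal node, ordered by rank.  This representation identifies a
#' ranked tree uniquely, so equality and hashing reduce to comparing
#' cluster sequences.
#'
#' `ranked_tree()` is the validating constructor.  It accepts the cluster
#' sequence (rank order) and, optionally, the leaf label set; when
#' `labels` is omitted it is inferred from the final (root) cluster.
#'
#' @param clusters list of character vectors, one per internal node in
#'   rank order; each is the set of leaf labels below that node.
#' @param labels optional character vector of all leaf labels.
#' @return An object of class `ranked_tree` with components `labels`
#'   (sorted), `clusters` (members sorted, rank order), `n`, and `merge`
#'   (an `(n-1) x 2` integer matrix giving, for each rank, the node ids of
#'   the two blocks merged there; leaf `i` has id `i` in sorted label
#'   order, the internal node of rank `t` has id `n + t`).
#' @examples
#' tr <- ranked_tree(list(
#'   c("a1", "a2"), c("a1", "a2", "a3"), c("a4", "a5"),
#'   c("a1", "a2", "a3", "a4", "a5")
#' ))
#' node_at_rank(tr, 3)
#' mrca_rank(tr, c("a1", "a3"))
#' @export
ranked_tree <- function(clusters, labels = NULL) {
  if (!is.list(clusters) || length(clusters) == 0L)
    rnni_abort("`clusters` must be a non-empty list of character vectors",
               "cluster_count")
  clusters <- lapply(clusters, function(cl) sort(unique(as.character(cl))))
  if (is.null(labels)) labels <- clusters[[length(clusters)]]
  labels <- as.character(labels)
  check_labels(labels)
  labels <- sort(labels)
  n <- length(labels)
  if (n < 2L)
    rnni_abort("a ranked tree needs at least 2 leaves", "labels")
  if (length(clusters) != n - 1L)
    rnni_abort(sprintf("expected %d clusters for %d leaves, got %d",
                       n - 1L, n, length(clusters)), "cluster_count")
  unknown <- setdiff(unique(unlist(clusters)), labels)
  if (length(unknown) > 0L)
    rnni_abort(paste0("cluster members outside the label set: ",
                      paste(unknown, collapse = ", ")), "unknown_label")
  if (!identical(clusters[[n - 1L]], labels))
    rnni_abort("the final (root) cluster must equal the full label set",
               "root")

  # merge-validity: grow a partition from singletons; each cluster must be
  # the union of exactly two current blocks, which it then replaces
  blk <- seq_len(n)                 # current block root id per leaf
  blk_size <- c(rep(1L, n), rep(NA_integer_, n - 1L))
  merge <- matrix(NA_integer_, n - 1L, 2L)
  for (k in seq_len(n - 1L)) {
    idx <- match(clusters[[k]], labels)
    if (length(idx) < 2L)
      rnni_abort(sprintf("cluster %d has fewer than 2 members", k),
                 "merge")
    roots <- unique(blk[idx])
    if (length(roots) != 2L)
      rnni_abort(sprintf(
        "cluster %d ({%s}) is not the union of exactly two current blocks",
        k, paste(clusters[[k]], collapse = ",")), "merge")
    if (blk_size[roots[1L]] + blk_size[roots[2L]] != length(idx))
      rnni_abort(sprintf(
        "cluster %d ({%s}) splits an existing block",
        k, paste(clusters[[k]], collapse = ",")), "merge")
    blk[idx] <- n + k
    blk_size[n + k] <- length(idx)
    merge[k, ] <- sort(roots)
  }
  new_ranked_tree(labels, clusters, merge)
}

# fast internal constructor; callers guarantee canonical, valid input
new_ranked_tree <- function(labels, clusters, merge) {
  structure(
    list(labels = labels, clusters = clusters, n = length(labels),
         merge = merge),
    class = "ranked_tree"
  )
}

check_labels <- function(labels) {
  if (length(labels) == 0L || anyNA(labels) ||
      !all(grepl("^[A-Za-z0-9_]+$", labels)))
    rnni_abort("labels must be non-empty strings over [A-Za-z0-9_]",
               "labels")
  if (anyDuplicated(labels))
    rnni_abort("duplicate leaf labels", "labels")
  invisible(labels)
}

rnni_abort <- function(msg, subclass) {
  stop(errorCondition(msg,
                      class = c(paste0("rnni_error_", subclass),
                                "rnni_error", "error", "condition")))
}

#' @export
print.ranked_tree <- function(x, ...) {
  cat("<ranked_tree> ", x$n, " leaves\n", sep = "")
  cat(format_clusters(x), "\n", sep = "")
  invisible(x)
}

#' Number of leaves of a ranked tree
#' @param tree a `ranked_tree`.
#' @return integer leaf count `n`.
#' @export
n_leaves <- function(tree) {
  stopifnot(inherits(tree, "ranked_tree"))
  tree$n
}

#' Cluster induced by the internal node of a given rank
#'
#' @param tree a `ranked_tree`.
#' @param t integer rank, `1 <= t <= n - 1`.
#' @return Character vector: the cluster induced by the node of rank `t`.
#' @export
node_at_rank <- function(tree, t) {
  stopifnot(inherits(tree, "ranked_tree"))
  t <- as.integer(t)
  if (length(t) != 1L || is.na(t) || t < 1L || t > tree$n - 1L)
    rnni_abort(sprintf("rank must lie in 1..%d", tree$n - 1L), "rank")
  tree$clusters[[t]]
}

#' Rank of the most recent common ancestor of a set of leaves
#'
#' Returns the rank of the lowest-ranked node whose cluster contains all
#' of `S`.  A single leaf is its own ancestor of rank 0.
#'
#' @param tree a `ranked_tree`.
#' @param S non-empty character vector of leaf labels.
#' @return Integer rank in `0..n-1`.
#' @export
mrca_rank <- function(tree, S) {
  stopifnot(inherits(tree, "ranked_tree"))
  S <- unique(as.character(S))
  if (length(S) == 0L)
    rnni_abort("`S` must be non-empty", "mrca")
  if (!all(S %in% tree$labels))
    rnni_abort(paste0("unknown labels in `S`: ",
                      paste(setdiff(S, tree$labels), collapse = ", ")),
               "unknown_label")
  if (length(S) == 1L) return(0L)
  for (t in seq_len(tree$n - 1L))
    if (all(S %in% tree$clusters[[t]])) return(t)
  stop("internal error: root cluster does not contain S")  # nocov
}

#' Identity of ranked trees
#'
#' Two ranked trees are identical iff there is an isomorphism preserving
#' edges, leaf labels and node ranks; equivalently, iff their cluster
#' representations agree rank by rank.
#'
#' @param x,y `ranked_tree` objects.
#' @return logical.
#' @export
tree_equal <- function(x, y) {
  stopifnot(inherits(x, "ranked_tree"), inherits(y, "ranked_tree"))
  identical(x$labels, y$labels) && identical(x$clusters, y$clusters)
}

#' @export
`==.ranked_tree` <- function(e1, e2) tree_equal(e1, e2)

#' @export
`!=.ranked_tree` <- function(e1, e2) !tree_equal(e1, e2)

#' Caterpillar tree in a given merge order
#'
#' Builds the fully imbalanced ("caterpillar") ranked tree whose clusters
#' are `{x1,x2}, {x1,x2,x3}, ..., {x1,...,xn}` for an input order
#' `x1..xn`.  Pairs of reversed caterpillars realise the worst-case
#' path length `(n-1)(n-2)/2` in the unit-weight RNNI graph.
#'
#' @param labels character vector of length >= 2; the merge order.
#' @return a `ranked_tree`.
#' @examples
#' caterpillar_tree(c("a1", "a2", "a3", "a4"))
#' @export
caterpillar_tree <- function(labels) {
  labels <- as.character(labels)
  check_labels(labels)
  n <- length(labels)
  if (n < 2L)
    rnni_abort("a caterpillar needs at least 2 labels", "labels")
  clusters <- lapply(2:n, function(k) sort(labels[seq_len(k)]))
  sorted <- sort(labels)
  ord <- match(labels, sorted)
  merge <- matrix(NA_integer_, n - 1L, 2L)
  merge[1L, ] <- sort(ord[1:2])
  if (n > 2L)
    for (k in 2:(n - 1L)) merge[k, ] <- sort(c(n + k - 1L, ord[k + 1L]))
  new_ranked_tree(sorted, clusters, merge)
}
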