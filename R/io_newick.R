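#' Read a ranked tree from an ultrametric Newick string
#'
#' Ranked trees carry no branch lengths, so the Newick interchange
#' convention here derives ranks from node times: with leaf time 0 and
#' node time = (maximum root-to-leaf path length) minus depth, the tree
#' must be ultrametric (all leaf times within `epsilon` of 0) and the
#' internal node times must be strictly ordered; their time order is the
#' rank order.  Ties (times closer than `epsilon`) are rejected under
#' `tie_policy = "error"` -- silently breaking them would fabricate a
#' ranking -- or, under `"lex"`, broken by the lexicographically
#' smallest descendant label (parent-child ties remain impossible to
#' rank and still error).
#'
#' @param s a single Newick string (rooted, binary, with branch
#'   lengths).
#' @param epsilon non-negative tolerance on times (default `1e-6`).
#' @param tie_policy `"error"` or `"lex"`.
#' @return a `ranked_tree`.
#' @examples
#' read_newick("((a1:1,a2:1):2,a3:3);")
#' @export
read_newick <- function(s, epsilon = 1e-6, tie_policy = c("error", "lex")) {
  tie_policy <- match.arg(tie_policy)
  if (!is.character(s) || length(s) != 1L || is.na(s))
    rnni_abort("`s` must be a single Newick string", "syntax")
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = s)),
                  error = function(e) NULL)
  if (is.null(phy) || inherits(phy, "multiPhylo"))
    rnni_abort("not a parsable single Newick tree", "syntax")
  n <- length(phy$tip.label)
  if (n < 2L) rnni_abort("need at least 2 leaves", "labels")
  if (!ape::is.rooted(phy) || !ape::is.binary(phy))
    rnni_abort("tree must be rooted and binary", "newick")
  if (is.null(phy$edge.length) ||
      length(phy$edge.length) != nrow(phy$edge) ||
      anyNA(phy$edge.length))
    rnni_abort("branch lengths are required on every edge", "newick")
  check_labels(phy$tip.label)

  depth <- ape::node.depth.edgelength(phy)
  times <- max(depth[seq_len(n)]) - depth
  if (any(abs(times[seq_len(n)]) > epsilon))
    rnni_abort(sprintf(
      "tree is not ultrametric: leaf times deviate up to %g (epsilon %g)",
      max(abs(times[seq_len(n)])), epsilon), "ultrametric")

  # leaf sets below each node, in node-id space
  below <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) below[[i]] <- phy$tip.label[i]
  po <- stats::reorder(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  ids <- (n + 1L):(2L * n - 1L)
  tint <- times[ids]
  if (any(tint <= epsilon))
    rnni_abort("an internal node is tied with the leaves (time ~ 0)",
               "tie")
  lexmin <- vapply(below[ids], min, character(1))
  ord <- order(tint, lexmin)
  gaps <- diff(tint[ord])
  if (any(gaps <= epsilon)) {
    if (tie_policy == "error")
      rnni_abort(
        "tied internal node times; rerank the input or use tie_policy = \"lex\"",
        "tie")
    # "lex": chain ties into groups, order each group lexicographically
    grp <- cumsum(c(0, gaps > epsilon))
    ord <- ord[order(grp, lexmin[ord])]
  }
  clusters <- lapply(below[ids][ord], sort)
  ranked_tree(clusters, phy$tip.label)
}

#' Write a ranked tree as an ultrametric Newick string
#'
#' The internal node of rank `t` is placed at time `t` (unit rank
#' spacing), leaves at time 0; branch lengths are the time differences.
#' Children are ordered by their smallest leaf label, making the output
#' deterministic.  `read_newick(write_newick(x))` recovers `x`.
#'
#' @param tree a `ranked_tree`.
#' @return a single Newick string.
#' @examples
#' write_newick(parse_clusters("[{a1,a2},{a1,a2,a3}]"))
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "ranked_tree"))
  n <- tree$n
  render <- function(id) {
    if (id <= n)
      return(list(str = tree$labels[id], time = 0, min = tree$labels[id]))
    t <- id - n
    kids <- lapply(tree$merge[t, ], render)
    if (kids[[2L]]$min < kids[[1L]]$min) kids <- rev(kids)
    parts <- vapply(kids, function(k)
      paste0(k$str, ":", format(t - k$time, scientific = FALSE)),
      character(1))
    list(str = paste0("(", paste(parts, collapse = ","), ")"),
         time = t, min = kids[[1L]]$min)
  }
  paste0(render(2L * n - 1L)$str, ";")
}
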