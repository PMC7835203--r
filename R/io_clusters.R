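#' Parse a cluster-representation string
#'
#' Reads a ranked tree from the textual cluster representation
#' `[{a1,a2},{a1,a2,a3},...]`: braces delimit clusters, written order is
#' rank order, labels are `[A-Za-z0-9_]+`, and whitespace between tokens
#' is ignored.  Syntax errors report the offending character position;
#' structurally well-formed input is then validated as a ranked tree.
#'
#' @param s a single string.
#' @param labels optional character vector of leaf labels; when omitted
#'   the label set is inferred from the final (root) cluster.
#' @return a `ranked_tree`.
#' @examples
#' parse_clusters("[{a1,a2},{a1,a2,a3},{a4,a5},{a1,a2,a3,a4,a5}]")
#' @export
parse_clusters <- function(s, labels = NULL) {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    rnni_abort("`s` must be a single string", "syntax")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  i <- 1L
  len <- length(chars)
  fail <- function(what) {
    rnni_abort(sprintf("cluster-string syntax error at position %d: %s",
                       min(i, len + 1L), what), "syntax")
  }
  skip_ws <- function() {
    while (i <= len && chars[i] %in% c(" ", "\t", "\r", "\n")) i <<- i + 1L
  }
  eat <- function(ch) {
    skip_ws()
    if (i > len || chars[i] != ch)
      fail(paste0("expected '", ch, "'"))
    i <<- i + 1L
  }
  peek <- function() {
    skip_ws()
    if (i > len) "" else chars[i]
  }
  label <- function() {
    skip_ws()
    j <- i
    while (j <= len && grepl("^[A-Za-z0-9_]$", chars[j])) j <- j + 1L
    if (j == i) fail("expected a label ([A-Za-z0-9_]+)")
    out <- paste(chars[i:(j - 1L)], collapse = "")
    i <<- j
    out
  }
  cluster <- function() {
    eat("{")
    members <- label()
    while (peek() == ",") {
      eat(",")
      members <- c(members, label())
    }
    eat("}")
    members
  }
  eat("[")
  clusters <- list(cluster())
  while (peek() == ",") {
    eat(",")
    clusters[[length(clusters) + 1L]] <- cluster()
  }
  eat("]")
  skip_ws()
  if (i <= len) fail("trailing characters after ']'")
  ranked_tree(clusters, labels)
}

#' Canonical cluster-representation string of a ranked tree
#'
#' Clusters in rank order, members lexicographically sorted, no
#' whitespace.  `parse_clusters(format_clusters(x))` is the identity,
#' and equal trees format identically, so the string doubles as a
#' canonical hash key.
#'
#' @param tree a `ranked_tree`.
#' @return a single string.
#' @export
format_clusters <- function(tree) {
  stopifnot(inherits(tree, "ranked_tree"))
  paste0("[", paste(vapply(
    tree$clusters,
    function(cl) paste0("{", paste(cl, collapse = ","), "}"),
    character(1)), collapse = ","), "]")
}
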