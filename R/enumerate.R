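#' Enumerate all ranked trees on a label set
#'
#' Generates every ranked tree on the given leaves by recursing over all
#' merge sequences: starting from singleton blocks, each rank merges one
#' of the `choose(k, 2)` unordered pairs of current blocks.  Merge
#' sequences are in bijection with ranked trees, so the output is
#' duplicate-free and has exactly `(n-1)! n! / 2^(n-1)` elements
#' (1, 3, 18, 180, 2700, 56700 for n = 2..7).
#'
#' @param labels character vector of leaf labels, or a single integer `n`
#'   (labels `a1..an` are then used).
#' @param cap maximum admissible `n` (default 7, 56,700 trees); the count
#'   grows super-exponentially, so larger label sets are refused.
#' @return list of `ranked_tree` objects.
#' @examples
#' length(enumerate_trees(4))  # 18
#' @export
enumerate_trees <- function(labels, cap = 7L) {
  labels <- default_labels(labels)
  n <- length(labels)
  if (n < 2L) rnni_abort("need at least 2 labels", "labels")
  if (n > cap)
    rnni_abort(sprintf("enumeration capped at n = %d (got n = %d)", cap, n),
               "cap")
  labels <- sort(labels)
  out <- vector("list", num_ranked_trees(n))
  pos <- 0L
  blocks0 <- as.list(labels)
  ids0 <- seq_len(n)

  recurse <- function(blocks, ids, clusters, merge, k) {
    m <- length(blocks)
    if (m == 1L) {
      pos <<- pos + 1L
      out[[pos]] <<- new_ranked_tree(labels, clusters, merge)
      return(invisible())
    }
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        merged <- sort(c(blocks[[i]], blocks[[j]]))
        clusters[[k]] <- merged
        merge[k, ] <- sort(c(ids[i], ids[j]))
        recurse(c(blocks[-c(i, j)], list(merged)),
                c(ids[-c(i, j)], n + k),
                clusters, merge, k + 1L)
      }
    }
  }
  recurse(blocks0, ids0, vector("list", n - 1L),
          matrix(NA_integer_, n - 1L, 2L), 1L)
  out
}

#' Number of ranked trees on n leaves
#'
#' Evaluates `(n-1)! n! / 2^(n-1)`.
#'
#' @param n integer leaf count.
#' @return numeric count.
#' @export
num_ranked_trees <- function(n) {
  factorial(n - 1) * factorial(n) / 2^(n - 1)
}

#' Uniform random ranked tree
#'
#' Samples uniformly over all ranked trees on the label set by drawing,
#' at each rank, a uniformly random unordered pair of current partition
#' blocks and merging them.  There are `prod(choose(k, 2), k = 2..n)`
#' such merge sequences, which equals the number of ranked trees, and
#' each sequence yields a distinct tree, so the draw is exactly uniform.
#'
#' @param labels character vector of leaf labels, or a single integer `n`
#'   for labels `a1..an`.
#' @param seed optional integer; when given, the sampler is deterministic
#'   and the caller's RNG state is left untouched.
#' @return a `ranked_tree`.
#' @examples
#' random_tree(5, seed = 1)
#' @export
random_tree <- function(labels, seed = NULL) {
  labels <- default_labels(labels)
  n <- length(labels)
  if (n < 2L) rnni_abort("need at least 2 labels", "labels")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  labels <- sort(labels)
  blocks <- as.list(labels)
  ids <- seq_len(n)
  clusters <- vector("list", n - 1L)
  merge <- matrix(NA_integer_, n - 1L, 2L)
  for (k in seq_len(n - 1L)) {
    m <- length(blocks)
    pick <- if (m == 2L) c(1L, 2L) else sort(sample.int(m, 2L))
    merged <- sort(c(blocks[[pick[1L]]], blocks[[pick[2L]]]))
    clusters[[k]] <- merged
    merge[k, ] <- sort(ids[pick])
    blocks <- c(blocks[-pick], list(merged))
    ids <- c(ids[-pick], n + k)
  }
  new_ranked_tree(labels, clusters, merge)
}

default_labels <- function(labels) {
  if (is.numeric(labels) && length(labels) == 1L)
    labels <- paste0("a", seq_len(as.integer(labels)))
  as.character(labels)
}
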