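test_that("validation accepts well-formed cluster sequences", {
  tr <- fig1_tree()
  expect_s3_class(tr, "ranked_tree")
  expect_equal(n_leaves(tr), 5L)
  expect_equal(tr$clusters[[3]], c("a4", "a5"))

  tiny <- ranked_tree(list(c("a1", "a2"), c("a1", "a2", "a3")))
  expect_equal(n_leaves(tiny), 3L)

  # member order and duplicates inside a cluster are normalised away
  same <- ranked_tree(list(c("a2", "a1", "a2"), c("a3", "a2", "a1")))
  expect_true(tree_equal(same, tiny))
})

test_that("validation rejects each malformation with its own error class", {
  labs4 <- paste0("a", 1:4)
  # nesting violation: a1 is locked inside block {a1,a2}
  expect_error(
    ranked_tree(list(c("a1", "a2"), c("a1", "a3", "a4"),
                     c("a1", "a2", "a3", "a4")), labs4),
    class = "rnni_error_merge")
  # wrong number of clusters
  expect_error(
    ranked_tree(list(c("a1", "a2")), labs4),
    class = "rnni_error_cluster_count")
  # root cluster must be the whole label set
  expect_error(
    ranked_tree(list(c("a1", "a2"), c("a1", "a2", "a3"),
                     c("a1", "a2", "a3")), labs4),
    class = "rnni_error_root")
  # labels outside the label set
  expect_error(
    ranked_tree(list(c("a1", "zz"), c("a1", "a2", "a3")),
                paste0("a", 1:3)),
    class = "rnni_error_unknown_label")
  # duplicate labels
  expect_error(
    ranked_tree(list(c("a1", "a2"), c("a1", "a2", "a3")),
                c("a1", "a1", "a2", "a3")),
    class = "rnni_error_labels")
  # a cluster that equals one existing block is not a union of two
  expect_error(
    ranked_tree(list(c("a1", "a2"), c("a1", "a2"),
                     c("a1", "a2", "a3", "a4")), labs4),
    class = "rnni_error_merge")
})

test_that("node_at_rank returns the rank-indexed cluster", {
  tr <- fig1_tree()
  expect_equal(node_at_rank(tr, 3), c("a4", "a5"))
  expect_equal(node_at_rank(tr, 4), paste0("a", 1:5))
  expect_error(node_at_rank(tr, 0), class = "rnni_error_rank")
  expect_error(node_at_rank(tr, 5), class = "rnni_error_rank")
})

test_that("mrca_rank finds the lowest covering cluster", {
  tr <- fig1_tree()
  expect_equal(mrca_rank(tr, c("a1", "a3")), 2L)
  expect_equal(mrca_rank(tr, c("a3", "a4")), 4L)
  expect_equal(mrca_rank(tr, "a1"), 0L)
  expect_error(mrca_rank(tr, character(0)), class = "rnni_error_mrca")
  expect_error(mrca_rank(tr, c("a1", "zz")),
               class = "rnni_error_unknown_label")
})

test_that("identity is cluster-sequence identity, ranks included", {
  tr <- fig1_tree()
  expect_true(tree_equal(tr, tr))
  expect_true(tr == parse_clusters(format_clusters(tr)))
  # the tree, its two NNI rearrangements on the lowest edge, and its rank
  # neighbour are four pairwise distinct trees
  four <- c(list(tr),
            lapply(nni_neighbours(tr, 1), `[[`, "tree"),
            list(apply_rank_move(tr, 2)))
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(tree_equal(four[[i]], four[[j]]))
  # swapping the ranks of two incomparable clusters changes the tree
  expect_true(tr != apply_rank_move(tr, 2))
})

test_that("caterpillar trees nest their clusters in input order", {
  ct <- caterpillar_tree(paste0("a", 1:5))
  expect_equal(format_clusters(ct),
               "[{a1,a2},{a1,a2,a3},{a1,a2,a3,a4},{a1,a2,a3,a4,a5}]")
  rev5 <- caterpillar_tree(c("a1", "a5", "a4", "a3", "a2"))
  expect_equal(rev5$clusters[[1]], c("a1", "a5"))
  expect_equal(rev5$clusters[[2]], c("a1", "a4", "a5"))
  expect_equal(format_clusters(caterpillar_tree(c("y", "x"))), "[{x,y}]")
  expect_error(caterpillar_tree("x"), class = "rnni_error_labels")
  for (t in seq_len(ct$n - 2)) expect_true(is_edge_interval(ct, t))
})

test_that("enumeration matches the closed-form count and is duplicate-free", {
  counts <- c(1, 3, 18, 180, 2700)
  for (n in 2:6) {
    trees <- enum_trees(n)
    expect_length(trees, counts[n - 1])
    expect_equal(length(trees), num_ranked_trees(n))
  }
  keys6 <- vapply(enum_trees(6), format_clusters, character(1))
  expect_equal(anyDuplicated(keys6), 0L)
  expect_error(enumerate_trees(8), class = "rnni_error_cap")
})

test_that("every enumerated tree survives a validate round trip (n <= 6)", {
  for (n in c(3, 6)) {
    for (tr in enum_trees(n)) {
      back <- ranked_tree(tr$clusters, tr$labels)
      expect_true(tree_equal(back, tr))
      expect_identical(back$merge, tr$merge)
    }
  }
})

test_that("clusters within a tree are pairwise nested or disjoint (n <= 5)", {
  for (n in 4:5) {
    for (tr in enum_trees(n)) {
      cl <- tr$clusters
      for (i in seq_along(cl)) for (j in seq_along(cl)) {
        if (i >= j) next
        inter <- length(intersect(cl[[i]], cl[[j]]))
        ok <- inter == 0L || inter == length(cl[[i]]) ||
          inter == length(cl[[j]])
        expect_true(ok)
      }
    }
  }
})

test_that("mrca of a tree's own cluster is its rank (n <= 5)", {
  for (tr in enum_trees(5)) {
    for (t in seq_len(tr$n - 1))
      expect_equal(mrca_rank(tr, tr$clusters[[t]]), t)
  }
})

test_that("random_tree is deterministic given a seed and leaves RNG alone", {
  expect_true(tree_equal(random_tree(6, seed = 42), random_tree(6, seed = 42)))
  expect_true(tree_equal(random_tree(2, seed = 1),
                         ranked_tree(list(c("a1", "a2")))))
  set.seed(7)
  before <- .Random.seed
  invisible(random_tree(10, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("random_tree samples ranked trees uniformly (n = 4)", {
  keys <- vapply(enum_trees(4), format_clusters, character(1))
  set.seed(424242)
  draws <- vapply(seq_len(18000),
                  function(i) format_clusters(random_tree(4)),
                  character(1))
  tab <- table(factor(draws, levels = keys))
  expect_equal(sum(tab), 18000)
  gof <- stats::chisq.test(tab)
  expect_gt(gof$p.value, 0.001)
})
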