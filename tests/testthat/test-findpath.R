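test_that("findpath_step picks the unique rank-lowering move", {
  # edge below the root: NNI pulling {a1,a3} together via {a1,a2,a3}
  T1 <- parse_clusters("[{a1,a2},{a3,a4},{a1,a2,a3,a4}]")
  s1 <- findpath_step(T1, c("a1", "a3"), 1)
  expect_equal(s1$move$kind, "nni")
  expect_equal(format_clusters(s1$tree),
               "[{a1,a2},{a1,a2,a3},{a1,a2,a3,a4}]")
  s2 <- findpath_step(s1$tree, c("a1", "a3"), 1)
  expect_equal(format_clusters(s2$tree),
               "[{a1,a3},{a1,a2,a3},{a1,a2,a3,a4}]")
  # from a caterpillar, lowering {a3,a4} starts by splitting off {a3,a4}
  T2 <- parse_clusters("[{a1,a2},{a1,a2,a3},{a1,a2,a3,a4}]")
  s3 <- findpath_step(T2, c("a3", "a4"), 2)
  expect_equal(s3$move$kind, "nni")
  expect_equal(format_clusters(s3$tree),
               "[{a1,a2},{a3,a4},{a1,a2,a3,a4}]")
  # a non-edge interval gets the rank move instead
  s4 <- findpath_step(s3$tree, c("a3", "a4"), 1)
  expect_equal(s4$move$kind, "rank")
  expect_equal(format_clusters(s4$tree),
               "[{a3,a4},{a1,a2},{a1,a2,a3,a4}]")
  expect_error(findpath_step(T2, c("a1", "a2"), 1),
               class = "rnni_error_step")
})

test_that("findpath reproduces the canonical 4-leaf NNI-rank-NNI path", {
  pr <- gap_pair_rank()
  p <- findpath(pr$T, pr$R)
  expect_equal(vapply(p$moves, `[[`, character(1), "kind"),
               c("nni", "rank", "nni"))
  expect_equal(vapply(path_trees(p), format_clusters, character(1)),
               c("[{a1,a2},{a1,a2,a3},{a1,a2,a3,a4}]",
                 "[{a1,a2},{a3,a4},{a1,a2,a3,a4}]",
                 "[{a3,a4},{a1,a2},{a1,a2,a3,a4}]",
                 "[{a3,a4},{a2,a3,a4},{a1,a2,a3,a4}]"))
})

test_that("findpath reproduces the canonical 4-leaf all-NNI path", {
  pr <- gap_pair_nni()
  p <- findpath(pr$T, pr$R)
  expect_equal(p$n_rank, 0)
  expect_equal(p$n_nni, 3)
  expect_equal(vapply(path_trees(p), format_clusters, character(1)),
               c("[{a1,a2},{a3,a4},{a1,a2,a3,a4}]",
                 "[{a1,a2},{a1,a2,a3},{a1,a2,a3,a4}]",
                 "[{a1,a3},{a1,a2,a3},{a1,a2,a3,a4}]",
                 "[{a1,a3},{a1,a3,a4},{a1,a2,a3,a4}]"))
})

test_that("findpath of a tree to itself is empty", {
  tr <- fig1_tree()
  p <- findpath(tr, tr)
  expect_length(p$moves, 0L)
  expect_equal(findpath_distance(tr, tr), 0)
  expect_error(findpath(tr, caterpillar_tree(c("x", "y"))),
               class = "rnni_error_labels")
})

test_that("reversed caterpillars attain the quadratic worst case", {
  for (n in c(4, 5, 10, 50, 100)) {
    T <- caterpillar_tree(paste0("a", 1:n))
    R <- caterpillar_tree(paste0("a", c(1, n:2)))
    p <- findpath(T, R)
    expect_equal(length(p$moves), (n - 1) * (n - 2) / 2)
    expect_equal(p$n_rank, 0)
    expect_equal(findpath_distance(T, R), (n - 1) * (n - 2) / 2)
  }
})

test_that("findpath agrees with BFS on the full 4-leaf tree space", {
  G <- oracle_graph(4)
  D <- oracle_all_distances(G)
  trees <- G$trees
  for (i in seq_along(trees)) for (j in seq_along(trees))
    expect_equal(findpath_distance(trees[[i]], trees[[j]]), D[i, j])
})

test_that("paths replay move by move and end at the destination", {
  # exhaustively on 4 leaves
  trees <- enum_trees(4)
  for (T in trees) for (R in trees) {
    p <- findpath(T, R)
    cur <- T
    for (m in p$moves) cur <- apply_move(cur, m)
    expect_true(tree_equal(cur, R))
    expect_lte(length(p$moves), (T$n - 1) * (T$n - 2) / 2)
  }
  # and on random pairs at n = 30, via the compact move-list replayer
  for (i in 1:200) {
    T <- random_tree(30, seed = 3000L + i)
    R <- random_tree(30, seed = 7000L + i)
    expect_true(rnni:::fp_replay_ok(T, R))
  }
  # the R-level move objects replay identically to the C-level replayer
  for (i in 1:10) {
    T <- random_tree(12, seed = 100L + i)
    R <- random_tree(12, seed = 200L + i)
    p <- findpath(T, R)
    final <- Reduce(apply_move, p$moves, accumulate = FALSE, init = T)
    expect_true(tree_equal(final, R))
  }
})

test_that("after iteration k the first k clusters match the destination", {
  # reconstructed from the path: moves within iteration k never touch
  # ranks below k, so the matched prefix never shrinks
  for (i in 1:20) {
    T <- random_tree(8, seed = 40L + i)
    R <- random_tree(8, seed = 80L + i)
    trees <- path_trees(findpath(T, R))
    prefix <- function(tr) {
      k <- 0L
      while (k < tr$n - 1 &&
             identical(tr$clusters[[k + 1]], R$clusters[[k + 1]]))
        k <- k + 1L
      k
    }
    pre <- vapply(trees, prefix, integer(1))
    expect_equal(pre[length(pre)], 7L)
    expect_equal(pre, cummax(pre))  # a matched prefix is never undone
  }
})

test_that("the RNNI(1) distance behaves as a metric on random triples", {
  for (i in 1:100) {
    a <- random_tree(10, seed = 3L * i)
    b <- random_tree(10, seed = 3L * i + 1L)
    c <- random_tree(10, seed = 3L * i + 2L)
    dab <- findpath_distance(a, b)
    expect_equal(dab, findpath_distance(b, a))
    expect_lte(dab, findpath_distance(a, c) + findpath_distance(c, b))
    expect_gte(dab, 0)
  }
})

test_that("a cluster shared by both trees is kept along the whole path", {
  for (i in 1:25) {
    pr <- shared_cluster_pair(10, 4, seed = 500L + 7L * i)
    expect_true(path_preserves_cluster(pr$T, pr$R, pr$shared))
  }
})

test_that("findpath weight is rho-independent in its move list", {
  pr <- gap_pair_rank()
  expect_equal(findpath_weight(pr$T, pr$R, rho = 2), 4)
  expect_equal(findpath_weight(pr$T, pr$R, rho = 0.25), 2.25)
  expect_equal(findpath_weight(pr$T, pr$R, rho = 1),
               findpath_distance(pr$T, pr$R))
  pr2 <- gap_pair_nni()
  for (rho in c(0, 0.5, 1, 4))
    expect_equal(findpath_weight(pr2$T, pr2$R, rho = rho), 3)
})
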