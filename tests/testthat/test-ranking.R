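g_ex <- example_network()

test_that("CumulativeRank reproduces the published scores and order", {
  r <- cumulative_rank(g_ex)
  expect_equal(r$node, table1_expected$node)
  expect_equal(rhu(r$score, 3), table1_expected$CR)
  expect_equal(rank_order(r), lapply(cr_order_expected, sort))
  expect_true(all(r$score >= 0))
  # dense ranks: start at 1, no gaps
  expect_equal(sort(unique(r$rank)), seq_len(max(r$rank)))
})

test_that("sum normalization matches the published table, sqrt does not", {
  r_sum <- cumulative_rank(g_ex, normalization = "sum")
  r_sqrt <- cumulative_rank(g_ex, normalization = "sqrt")
  expect_equal(rhu(r_sum$score, 3), table1_expected$CR)
  expect_false(isTRUE(all.equal(rhu(r_sqrt$score, 3), table1_expected$CR)))
  # both modes agree on the most influential node
  expect_equal(r_sum$node[which.min(r_sum$score)], "H")
  expect_equal(r_sqrt$node[which.min(r_sqrt$score)], "H")
})

test_that("CR reduces to its local term when no node is globally distinguished", {
  k4 <- igraph::make_full_graph(4)
  expect_message(r <- cumulative_rank(k4), "local term")
  ls <- local_scores(k4)
  expect_equal(r$score, ls$INCC / sum(ls$INCC), tolerance = 1e-12)
})

test_that("CR is invariant under relabelling", {
  g <- random_connected_gnp(n = 14, p = 0.22, seed = 11)
  g2 <- igraph::permute(g, sample(igraph::vcount(g)))
  r1 <- cumulative_rank(g)
  r2 <- cumulative_rank(g2)
  m <- match(r1$node, r2$node)
  expect_equal(r1$score, r2$score[m], tolerance = 1e-12)
  expect_equal(r1$rank, r2$rank[m])
})

test_that("degree-0 nodes are ranked last with a warning", {
  g <- igraph::make_ring(4)
  igraph::V(g)$name <- letters[1:4]
  g <- g + igraph::vertex("Z")
  expect_warning(r <- cumulative_rank(g), "ranked last")
  expect_equal(r$node[which.max(r$rank)], "Z")
})

test_that("top_k respects rank order and breaks ties lexicographically", {
  r <- cumulative_rank(g_ex)
  expect_equal(top_k(r, 5), c("H", "K", "G", "C", "F"))
  expect_equal(top_k(r, 1), "H")
  expect_setequal(top_k(r, 15), LETTERS[1:15])
  expect_equal(top_k(r, 11), c("H", "K", "G", "C", "F", "B", "A", "D", "E",
                               "I", "J"))
  expect_error(top_k(r, 16), "between 1 and")
  expect_error(top_k(r, 0), "between 1 and")
  # single-edge graph: one tied group of 2
  k2 <- igraph::make_graph(c("a", "b"), directed = FALSE)
  expect_message(rk2 <- cumulative_rank(k2))
  expect_equal(rank_order(rk2), list(c("a", "b")))
})

test_that("benchmark centralities match closed forms on small graphs", {
  star <- igraph::make_star(5, mode = "undirected")
  dc <- benchmark_centrality(star, "dc")
  expect_equal(dc$score[dc$node == "1"], 1) # centre: 4/(5-1)
  expect_equal(dc$rank[dc$node == "1"], 1)

  path3 <- igraph::make_graph(c("a", "b", "b", "c"), directed = FALSE)
  bc <- benchmark_centrality(path3, "bc")
  expect_equal(bc$score[bc$node == "b"], 1)

  lr <- benchmark_centrality(g_ex, "lr")
  expect_equal(lr$score, table1_expected$LR)
  expect_equal(lr$node[lr$rank == 1], "G")

  ec <- benchmark_centrality(g_ex, "ec")
  expect_equal(max(ec$score), 1) # unit max-norm

  expect_error(benchmark_centrality(g_ex, "xx"))
})

test_that("PageRank mass is conserved", {
  for (s in 1:10) {
    g <- random_gnp(n = 40, p = 0.1, seed = 700 + s, min_degree = 1)
    pr <- benchmark_centrality(g, "pr")
    expect_equal(sum(pr$score), 1, tolerance = 1e-8)
  }
  # dangling nodes redistribute uniformly; mass still sums to 1
  g_iso <- igraph::make_ring(5)
  igraph::V(g_iso)$name <- letters[1:5]
  g_iso <- g_iso + igraph::vertex("Z")
  pr2 <- benchmark_centrality(g_iso, "pr")
  expect_equal(sum(pr2$score), 1, tolerance = 1e-8)
})

test_that("benchmarks agree with the igraph reference to 1e-8", {
  for (s in 1:20) {
    g <- random_connected_gnp(n = 25, p = 0.15, seed = 900 + s)
    expect_equal(benchmark_centrality(g, "bc")$score,
                 unname(igraph::betweenness(g)), tolerance = 1e-8)
    expect_equal(benchmark_centrality(g, "ec")$score,
                 unname(igraph::eigen_centrality(g)$vector),
                 tolerance = 1e-8)
    expect_equal(benchmark_centrality(g, "pr")$score,
                 unname(igraph::page_rank(g, damping = 0.85)$vector),
                 tolerance = 1e-8)
    expect_equal(benchmark_centrality(g, "dc")$score,
                 unname(igraph::degree(g)) / (igraph::vcount(g) - 1),
                 tolerance = 1e-12)
  }
})

test_that("betweenness agrees with the hand-written path-counting oracle", {
  for (s in 1:10) {
    g <- generate_synthetic("erdos_renyi", n = 15, param = 0.2,
                            seed = 1100 + s)
    expect_equal(benchmark_centrality(g, "bc")$score, oracle_betweenness(g),
                 tolerance = 1e-8)
  }
})

test_that("eigenvector centrality on disconnected input reports the giant", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_ring(3))
  expect_message(ec <- benchmark_centrality(g, "ec"), "largest component")
  expect_equal(ec$score[1:5], rep(1, 5), tolerance = 1e-9)
  expect_equal(ec$score[6:8], rep(0, 3))
})
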