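test_that("binarization keeps retained edges and is idempotent", {
  C <- proportional_threshold(fake_connectivity(seed = 2), 0.30)
  g <- brain_graph(C)
  expect_equal(sum(g$adjacency[upper.tri(g$adjacency)]), 69)
  expect_identical(brain_graph(g$adjacency)$adjacency, g$adjacency)
  empty <- brain_graph(matrix(0, 4, 4))
  expect_equal(sum(empty$adjacency), 0)
  asym <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(brain_graph(asym), "symmetric")
})

test_that("analytic fixtures hit their closed-form metric values", {
  k4 <- brain_graph(complete_graph(4))
  expect_true(all(degree_centrality(k4) == 1))
  expect_true(all(betweenness_centrality(k4) == 0))
  expect_true(all(clustering_coefficient(k4) == 1))
  expect_true(all(local_efficiency(k4) == 1))
  expect_equal(global_efficiency(k4), 1)

  star5 <- brain_graph(star_graph(5))
  dc <- degree_centrality(star5)
  expect_equal(unname(dc), c(1, rep(0.25, 4)))
  expect_equal(unname(local_efficiency(star5))[1], 0)   # leaves unlinked

  p3 <- brain_graph(path_graph(3))
  bc <- betweenness_centrality(p3)
  expect_equal(unname(bc), c(0, 1, 0))
  expect_equal(unname(clustering_coefficient(p3))[2], 0)
  expect_equal(global_efficiency(p3), 5 / 6)

  edgeless <- brain_graph(matrix(0, 5, 5))
  expect_equal(global_efficiency(edgeless), 0)
  expect_true(all(degree_centrality(edgeless) == 0))
})

test_that("all five metrics match exhaustive oracles on random graphs", {
  for (seed in 1:20) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n, p = runif(1, 0.2, 0.7), seed = 100 + seed)
    g <- brain_graph(adj)
    expect_equal(unname(degree_centrality(g)), rowSums(adj) / (n - 1))
    expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(adj),
                 tolerance = 1e-12)
    expect_equal(unname(clustering_coefficient(g)), oracle_clustering(adj))
    expect_equal(unname(local_efficiency(g)), oracle_local_efficiency(adj))
    expect_equal(global_efficiency(g), oracle_global_efficiency(adj))
  }
})

test_that("adding an edge never decreases global efficiency or degree", {
  for (seed in 1:10) {
    adj <- random_adjacency(8, p = 0.3, seed = 200 + seed)
    missing <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
    if (!nrow(missing)) next
    pick <- missing[sample(nrow(missing), 1), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1
    expect_gte(global_efficiency(brain_graph(adj2)),
               global_efficiency(brain_graph(adj)))
    expect_true(all(degree_centrality(brain_graph(adj2)) >=
                      degree_centrality(brain_graph(adj))))
  }
})

test_that("metrics are invariant under node relabelling", {
  adj <- random_adjacency(7, p = 0.4, seed = 31)
  set.seed(32)
  perm <- sample(7)
  padj <- adj[perm, perm]
  for (metric in list(degree_centrality, betweenness_centrality,
                      clustering_coefficient, local_efficiency)) {
    expect_equal(unname(metric(brain_graph(padj))),
                 unname(metric(brain_graph(adj)))[perm])
  }
  expect_equal(global_efficiency(brain_graph(padj)),
               global_efficiency(brain_graph(adj)))
})

test_that("node metric table collects all metrics with annotation", {
  g <- brain_graph(random_adjacency(6, seed = 40))
  tbl <- node_metric_table(g, band = "theta", group = "hc")
  expect_equal(nrow(tbl), 6)
  expect_named(tbl, c("node", "degree_centrality", "betweenness_centrality",
                      "clustering_coefficient", "local_efficiency",
                      "band", "group"))
  expect_true(is.numeric(attr(tbl, "global_efficiency")))
  expect_error(degree_centrality(brain_graph(matrix(0, 1, 1))), "2 nodes")
})
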