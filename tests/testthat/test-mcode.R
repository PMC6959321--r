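test_that("k_core prunes iteratively and matches igraph coreness", {
  expect_equal(igraph::vcount(k_core(named_clique(5), 4)), 5L)
  path5 <- graph_from_edges(data.frame(from = c("a", "b", "c", "d"),
                                       to = c("b", "c", "d", "e")))
  expect_equal(igraph::vcount(k_core(path5, 2)), 0L)
  # 4-clique plus pendant: the 2-core is the clique
  g <- igraph::add_edges(igraph::add_vertices(named_clique(4), 1,
                                              name = "pend"),
                         c("v1", "pend"))
  core <- k_core(g, 2)
  expect_setequal(igraph::V(core)$name, paste0("v", 1:4))
  # oracle: vertices of coreness >= k (igraph) are exactly the k-core
  set.seed(2)
  rg <- igraph::sample_gnp(40, 0.1)
  igraph::V(rg)$name <- paste0("n", 1:40)
  for (k in 1:4) {
    mine <- sort(igraph::V(k_core(rg, k))$name)
    ref <- sort(igraph::V(rg)$name[igraph::coreness(rg) >= k])
    expect_equal(mine, ref)
  }
})

test_that("vertex weights reflect neighbourhood core density", {
  cl5 <- named_clique(5)
  expect_equal(vertex_weight(cl5, "v1"), 4)  # K5 neighbourhood: 4-core, density 1
  star <- graph_from_edges(data.frame(from = "hub", to = paste0("l", 1:4)))
  expect_equal(vertex_weight(star, "hub"), 0)
  expect_equal(vertex_weight(star, "hub", mode = "simple_clustering"), 0)
  tri <- named_clique(3)
  expect_equal(vertex_weight(tri, "v2", mode = "simple_clustering"), 1)
  expect_error(vertex_weight(cl5, "nope"), "unknown node")
  w <- mcode_weights(cl5)
  expect_equal(unname(w), rep(4, 5))
})

test_that("seed expansion respects the weight threshold and visited-once rule", {
  cl <- named_clique(6)
  res <- run_mcode(cl)
  expect_length(res, 1L)
  expect_setequal(res[[1]]$members, paste0("v", 1:6))

  expect_length(run_mcode(igraph::make_empty_graph(5, directed = FALSE)), 0L)

  # two cliques joined by one bridge: every clique vertex weighs the same,
  # so the expansion crosses the bridge and returns one merged cluster
  a <- named_clique(5, "a")
  b <- named_clique(5, "b")
  ab <- igraph::add_edges(igraph::disjoint_union(a, b), c("a1", "b1"))
  merged <- run_mcode(ab)
  expect_length(merged, 1L)
  expect_length(merged[[1]]$members, 10L)
})

test_that("post-processing discards coreless clusters and haircuts pendants", {
  g <- igraph::add_edges(igraph::add_vertices(named_clique(4), 1, name = "pend"),
                         c("v1", "pend"))
  res <- run_mcode(g)
  expect_length(res, 1L)
  expect_setequal(res[[1]]$members, paste0("v", 1:4))  # pendant haircut

  params_nohair <- mcode_params(haircut = FALSE)
  res2 <- run_mcode(g, params_nohair)
  # without haircut the pendant stays only if its weight passes the threshold;
  # its neighbourhood has edges (v1's clique) but the cluster must keep a 2-core
  expect_true(all(paste0("v", 1:4) %in% res2[[1]]$members))

  path3 <- graph_from_edges(data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_length(run_mcode(path3), 0L)  # no 2-core anywhere
})

test_that("cluster scores are density times size and ranking is deterministic", {
  cl5 <- named_clique(5)
  expect_equal(score_cluster(cl5, paste0("v", 1:5)), 5)
  cyc4 <- graph_from_edges(data.frame(from = c("a", "b", "c", "d"),
                                      to = c("b", "c", "d", "a")))
  expect_equal(score_cluster(cyc4, c("a", "b", "c", "d")), 4 / 6 * 4)
  expect_equal(score_cluster(cl5, "v1"), 0)

  two <- igraph::disjoint_union(named_clique(6, "a"), named_clique(4, "b"))
  res <- run_mcode(two)
  expect_equal(clusters_summary(res)$n_nodes, c(6L, 4L))
  expect_equal(res[[1]]$rank, 1L)
  res_again <- run_mcode(two)
  expect_identical(clusters_summary(res), clusters_summary(res_again))
})

test_that("a disjoint union of cliques is recovered exactly", {
  sizes <- c(7, 5, 4, 3)
  gs <- lapply(seq_along(sizes), function(i) {
    named_clique(sizes[i], prefix = paste0("c", i, "_"))
  })
  g <- Reduce(igraph::disjoint_union, gs)
  res <- run_mcode(g)
  expect_equal(clusters_summary(res)$n_nodes, sizes)
  for (i in seq_along(sizes)) {
    expect_setequal(res[[i]]$members, igraph::V(gs[[i]])$name)
  }
  # every cluster retains a 2-core and internal min degree >= 2 (haircut)
  for (cl in res) {
    sub <- igraph::induced_subgraph(g, cl$members)
    expect_gte(min(igraph::degree(sub)), 2)
  }
})

test_that("cluster membership TSV export is well-formed", {
  res <- run_mcode(igraph::disjoint_union(named_clique(5, "a"),
                                          named_clique(4, "b")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clusters(res, path)
  df <- read.delim(path)
  expect_named(df, c("cluster_id", "node", "score", "rank"))
  expect_equal(nrow(df), 9L)
})
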