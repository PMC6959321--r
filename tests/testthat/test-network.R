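make_tab <- function(m) otu_table(m)

test_that("abundance filter keeps exactly the rows at or above threshold", {
  m <- rbind(a_1 = rep(c(9L, 10L), c(2, 1)),  # total 28
             b_2 = c(10L, 10L, 10L),          # total 30
             c_3 = c(10L, 10L, 11L))          # total 31
  m[1, ] <- c(9L, 9L, 11L)  # total 29
  colnames(m) <- paste0("s", 1:3)
  tab <- make_tab(m)
  filt <- filter_low_abundance(tab, 30)
  expect_equal(rownames(filt), c("b_2", "c_3"))
  expect_identical(unclass(filter_low_abundance(tab, 0)), unclass(tab))
  expect_warning(filter_low_abundance(tab, 1e6), "all OTUs removed")
})

test_that("build_network applies inclusive |R| and p criteria and drops isolates", {
  set.seed(5)
  base <- rpois(20, 50)
  m <- rbind(a_1 = base,
             b_2 = base + rpois(20, 3),         # strongly concordant with a_1
             c_3 = rpois(20, 50))               # independent
  colnames(m) <- paste0("s", 1:20)
  net <- build_network(make_tab(m))
  expect_equal(sort(igraph::V(net)$name), c("a_1", "b_2"))
  expect_equal(igraph::ecount(net), 1L)
  expect_equal(igraph::E(net)$sign, "positive")
  keep_iso <- build_network(make_tab(m), drop_isolated = FALSE)
  expect_equal(igraph::vcount(keep_iso), 3L)
  expect_error(build_network(make_tab(m[1, , drop = FALSE])), "at least 2")
})

test_that("an edge exactly at r_min is retained (boundary inclusive)", {
  # construct a pair whose Spearman is known: use the rank vectors directly
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  y <- c(2, 1, 3, 4, 5, 6, 7, 8, 10, 9)
  r <- spearman_with_p(x, y)$r
  m <- rbind(a_1 = as.integer(x * 10), b_2 = as.integer(y * 10))
  colnames(m) <- paste0("s", 1:10)
  net <- build_network(make_tab(m), r_min = r, p_max = 0.05)
  expect_equal(igraph::ecount(net), 1L)
  expect_equal(igraph::E(net)$r, r, tolerance = 1e-12)
})

test_that("raising r_min never adds edges", {
  sim <- simulate_counts(simulation_spec(block_sizes = c(6, 6),
                                         n_background = 8, n_rare = 0,
                                         seed = 21))
  tab <- sim$table
  prev <- Inf
  for (rmin in c(0.4, 0.6, 0.8)) {
    ne <- igraph::ecount(build_network(tab, r_min = rmin))
    expect_lte(ne, prev)
    prev <- ne
  }
})

test_that("local clustering follows C_i = 2n / (k_i (k_i - 1))", {
  cl4 <- named_clique(4)
  expect_equal(local_clustering(cl4, "v1"), 1)
  star <- graph_from_edges(data.frame(from = "hub", to = c("a", "b", "c")))
  expect_equal(local_clustering(star, "hub"), 0)
  expect_equal(local_clustering(star, "a"), 0)  # degree < 2
  # k_i = 3, n = 2 -> 2*2/(3*2)
  g <- graph_from_edges(data.frame(from = c("x", "x", "x", "a", "b"),
                                   to = c("a", "b", "c", "b", "c")))
  expect_equal(local_clustering(g, "x"), 2 * 2 / (3 * 2))
  expect_error(local_clustering(g, "nope"), "unknown node")
  # cross-check against igraph on a random graph
  set.seed(8)
  rg <- igraph::sample_gnp(25, 0.25)
  igraph::V(rg)$name <- paste0("n", 1:25)
  mine <- vapply(igraph::V(rg)$name, function(v) local_clustering(rg, v), 0)
  ref <- igraph::transitivity(rg, type = "localundirected", isolates = "zero")
  ref[is.na(ref)] <- 0
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
})

test_that("pn_ratio covers finite, infinite, and undefined cases", {
  expect_equal(round(pn_ratio(3692, 643), 3), 5.742)
  expect_identical(pn_ratio(85, 0), Inf)
  expect_identical(pn_ratio(0, 0), NA_real_)
  expect_equal(pn_ratio(0, 5), 0)
  expect_error(pn_ratio(-1, 2), "non-negative")
})

test_that("network_stats matches closed forms and path-graph values", {
  path5 <- graph_from_edges(data.frame(from = c("a", "b", "c", "d"),
                                       to = c("b", "c", "d", "e")))
  igraph::E(path5)$sign <- "positive"
  st <- network_stats(path5)
  expect_equal(st$diameter, 4)
  expect_equal(st$average_path_length, 2)
  expect_equal(st$density, 0.4)
  expect_equal(st$average_degree, 2 * 4 / 5)
  expect_equal(st$n_components, 1)
  expect_equal(st$n_positive + st$n_negative, st$n_edges)

  set.seed(14)
  rg <- igraph::sample_gnp(40, 0.12)
  igraph::V(rg)$name <- paste0("n", 1:40)
  igraph::E(rg)$sign <- sample(c("positive", "negative"), igraph::ecount(rg),
                               replace = TRUE)
  st2 <- network_stats(rg)
  expect_equal(st2$average_degree, 2 * st2$n_edges / st2$n_nodes)
  expect_equal(st2$density, 2 * st2$n_edges / (st2$n_nodes * (st2$n_nodes - 1)))
  expect_equal(st2$pn_ratio, pn_ratio(st2$n_positive, st2$n_negative))
  expect_true(all(vapply(igraph::V(rg)$name,
                         function(v) local_clustering(rg, v), 0) >= 0))
})

test_that("edge list export round-trips through TSV", {
  sim <- simulate_counts(simulation_spec(block_sizes = c(5, 5), n_background = 2,
                                         n_rare = 0, seed = 4, n_samples = 40))
  net <- build_network(sim$table)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read.delim(path)
  expect_equal(nrow(back), igraph::ecount(net))
  expect_named(back, c("source", "target", "r", "p_value", "sign"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(reread), igraph::ecount(net))
})
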