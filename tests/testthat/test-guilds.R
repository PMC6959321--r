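signed_graph <- function(..., vertices = NULL) {
  graph_from_edges(signed_edges(...), vertices = vertices)
}

test_that("positive-edge union-find recovers planted sign-coherent groups", {
  p <- partition_subguilds(signed_graph("a+b", "c+d", "a-c", "b-d"))
  expect_length(p$groups, 2L)
  expect_setequal(p$groups[[1]], c("a", "b"))
  expect_setequal(p$groups[[2]], c("c", "d"))
  expect_true(p$balanced)
  expect_equal(nrow(p$frustrated_edges), 0L)

  p2 <- partition_subguilds(signed_graph("a+b", "a-c", "b-c"))
  expect_equal(lengths(p2$groups), c(2L, 1L))
  expect_true(p2$balanced)

  # negative edge inside a positively-connected group is frustrated
  p3 <- partition_subguilds(signed_graph("a+b", "b+c", "a-c"))
  expect_length(p3$groups, 1L)
  expect_false(p3$balanced)
  expect_equal(nrow(p3$frustrated_edges), 1L)
  expect_equal(p3$frustrated_edges$sign, "negative")

  # all-negative triangle: weakly balanced as three singleton groups
  p4 <- partition_subguilds(signed_graph("a-b", "a-c", "b-c"))
  expect_length(p4$groups, 3L)
  expect_true(p4$balanced)
})

test_that("union-find frustration matches exhaustive set-partition minimum", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:8, 1)
    vertices <- letters[1:n]
    # planted two-group sign pattern over a random connected-ish graph
    grp <- sample(rep(1:2, length.out = n))
    pairs <- t(combn(vertices, 2))
    keep <- runif(nrow(pairs)) < 0.7
    # ensure positive spanning structure within each group
    edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                        stringsAsFactors = FALSE)
    gi <- grp[match(edges$from, vertices)]
    gj <- grp[match(edges$to, vertices)]
    edges$sign <- ifelse(gi == gj, "positive", "negative")
    flipped <- FALSE
    if (rep %% 2 == 0 && any(edges$sign == "positive")) {
      # perturb: one within-group tie turns hostile
      k <- sample(which(edges$sign == "positive"), 1)
      edges$sign[k] <- "negative"
      flipped <- TRUE
    }
    edges$r <- ifelse(edges$sign == "positive", 0.8, -0.8)
    g <- graph_from_edges(edges, vertices = data.frame(name = vertices))
    p <- partition_subguilds(g)
    expect_equal(nrow(p$frustrated_edges),
                 oracle_min_frustration(edges, vertices))
    if (!flipped) {
      expect_true(p$balanced)
      # membership must refine the planted grouping on balanced patterns:
      # every recovered group lies inside one planted group
      for (gset in p$groups) {
        expect_length(unique(grp[match(gset, vertices)]), 1L)
      }
    }
  }
})

test_that("roles partition the cluster into guards, civilians, anomalous", {
  g <- signed_graph("a+b", "b+c", "c+d", "e+f", "a-e", "b-f")
  p <- partition_subguilds(g)
  roles <- classify_roles(g, p)
  expect_setequal(roles$node, c("a", "b", "c", "d", "e", "f"))
  expect_setequal(roles$node[roles$role == "guard"], c("a", "b", "e", "f"))
  expect_setequal(roles$node[roles$role == "civilian"], c("c", "d"))

  all_pos <- signed_graph("a+b", "b+c", "a+c")
  rp <- classify_roles(all_pos, partition_subguilds(all_pos))
  expect_true(all(rp$role == "civilian"))

  frus <- signed_graph("a+b", "b+c", "a-c")
  rf <- classify_roles(frus, partition_subguilds(frus))
  expect_setequal(rf$node[rf$role == "anomalous"], c("a", "c"))
  # the three classes always cover all nodes
  expect_equal(sort(rf$node), c("a", "b", "c"))
})

test_that("negative edges of a balanced cluster join two guards", {
  sim <- simulate_counts(simulation_spec(n_samples = 150, seed = 6))
  res <- run_pipeline(sim$table, pipeline_config(), quiet = TRUE)
  rep <- res$report
  if (rep$partition$balanced) {
    sub <- igraph::induced_subgraph(res$network, rep$members)
    el <- igraph::as_edgelist(sub)
    neg <- igraph::E(sub)$sign == "negative"
    role_of <- setNames(rep$roles$role, rep$roles$node)
    expect_true(all(role_of[el[neg, 1]] == "guard"))
    expect_true(all(role_of[el[neg, 2]] == "guard"))
  }
  expect_true(all(rep$roles$role %in% c("guard", "civilian", "anomalous")))
  expect_setequal(rep$roles$node, rep$members)
})

test_that("phylum composition counts and rounds like printed tables", {
  roles <- load_fba_roles()
  taxonomy <- setNames(roles$phylum_group, roles$node)
  comp <- phylum_composition(roles$node, taxonomy)
  expect_equal(comp$n, c(21L, 14L, 9L, 11L))
  expect_equal(comp$percent, c(38.2, 25.5, 16.4, 20.0))
  asg <- roles$node[roles$sub_guild == "ASG"]
  comp_asg <- phylum_composition(asg, taxonomy)
  expect_equal(comp_asg$n, c(14L, 0L, 2L, 5L))
  expect_equal(comp_asg$percent, c(66.7, 0, 9.5, 23.8))
  fbsg <- roles$node[roles$sub_guild == "FBSG"]
  expect_equal(phylum_composition(fbsg, taxonomy)$percent,
               c(20.6, 41.2, 20.6, 17.6))
  expect_equal(nrow(phylum_composition(character(0), taxonomy)), 0L)
})

test_that("phylum-pair summary conserves edges and excludes diagonal by default", {
  g <- fba_guild_graph()
  taxonomy <- setNames(igraph::V(g)$phylum_group, igraph::V(g)$name)
  inter <- phylum_pair_summary(g, taxonomy)
  expect_true(all(inter$phylum_a != inter$phylum_b))
  expect_equal(inter$n_total, inter$n_positive + inter$n_negative)
  full <- phylum_pair_summary(g, taxonomy, include_within = TRUE)
  expect_equal(sum(full$n_total), igraph::ecount(g))
  af <- inter[inter$phylum_a == "Actinobacteria" & inter$phylum_b == "Firmicutes", ]
  expect_equal(af$n_negative, 13L)
})

test_that("guild_report bundles partition, roles, composition, dominance", {
  sim <- simulate_counts(simulation_spec(n_samples = 200, seed = 2))
  res <- run_pipeline(sim$table, pipeline_config(), quiet = TRUE)
  rep <- res$report
  expect_s3_class(rep, "guild_report")
  expect_equal(sum(vapply(rep$group_composition, function(x) sum(x$n), 0L)),
               length(rep$members))
  expect_length(rep$dominant_phylum, length(rep$partition$groups))
  expect_equal(length(rep$guard_counts), length(rep$partition$groups))
  # planted taxonomy: block 1 uses Actinobacteria genera, so its recovered
  # sub-guild must be Actinobacteria-dominant
  truth <- sim$truth$assignments
  b1 <- truth$otu[!is.na(truth$block) & truth$block == 1]
  grp_of_b1 <- unique(rep$partition$membership[b1])
  dom <- rep$dominant_phylum[[grp_of_b1]]
  expect_equal(dom$phylum, "Actinobacteria")

  json <- withr::local_tempfile(fileext = ".json")
  write_guild_report(rep, json)
  parsed <- jsonlite::read_json(json)
  expect_equal(length(parsed$members), length(rep$members))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_node_roles(rep, tsv)
  expect_named(read.delim(tsv), c("node", "sub_guild", "role", "phylum"))
})
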