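#' MCODE parameter set
#'
#' Parameters of the MCODE cluster detection algorithm. `vwp` (vertex weight
#' percentage, in \[0,1\]) controls how far below the seed weight a vertex may
#' lie and still join the seed's cluster; `haircut` iteratively removes
#' singly-connected cluster members; `fluff` optionally adds dense boundary
#' neighbours; `kcore_filter` discards clusters that do not contain a k-core of
#' that order; `max_depth` bounds the breadth-first expansion distance from the
#' seed. `weight_mode` selects the vertex weighting: `"core_density"` (default)
#' weights a vertex by `k_max * density` of the highest k-core of its closed
#' neighbourhood, `"simple_clustering"` uses the plain local clustering
#' coefficient `C_i`. The two modes differ because the clustering coefficient
#' ignores how cohesive the densest part of the neighbourhood is; the
#' core-density weighting is the canonical choice.
#'
#' @param vwp vertex weight percentage in \[0, 1\] (default 0.2).
#' @param haircut logical (default TRUE).
#' @param fluff logical (default FALSE).
#' @param fluff_density_cutoff density threshold for fluffed neighbours
#'   (default 0.1).
#' @param kcore_filter minimum core order a reported cluster must contain
#'   (default 2; must be >= 2).
#' @param max_depth maximum BFS depth from the seed (default 100).
#' @param weight_mode `"core_density"` or `"simple_clustering"`.
#' @return A list of class `mcode_params`.
#' @export
mcode_params <- function(vwp = 0.2, haircut = TRUE, fluff = FALSE,
                         fluff_density_cutoff = 0.1, kcore_filter = 2L,
                         max_depth = 100L,
                         weight_mode = c("core_density", "simple_clustering")) {
  weight_mode <- match.arg(weight_mode)
  if (vwp < 0 || vwp > 1) stop("vwp must be in [0, 1]")
  if (kcore_filter < 2) stop("kcore_filter must be >= 2")
  if (max_depth < 1) stop("max_depth must be >= 1")
  structure(list(vwp = vwp, haircut = haircut, fluff = fluff,
                 fluff_density_cutoff = fluff_density_cutoff,
                 kcore_filter = as.integer(kcore_filter),
                 max_depth = as.integer(max_depth),
                 weight_mode = weight_mode),
            class = "mcode_params")
}

#' Maximal k-core of a graph
#'
#' Iteratively prunes vertices of degree < k until every remaining vertex has
#' degree >= k; the (possibly empty) remainder is the k-core.
#'
#' @param graph an igraph object.
#' @param k non-negative integer.
#' @return The induced subgraph forming the k-core (may have zero vertices).
#' @export
k_core <- function(graph, k) {
  if (k < 0) stop("k must be >= 0")
  g <- graph
  repeat {
    low <- which(igraph::degree(g) < k)
    if (!length(low) || igraph::vcount(g) == 0) break
    g <- igraph::delete_vertices(g, low)
  }
  g
}

graph_density <- function(g) {
  v <- igraph::vcount(g)
  if (v < 2) return(0)
  2 * igraph::ecount(g) / (v * (v - 1))
}

#' MCODE vertex weight
#'
#' In `"core_density"` mode the weight of a vertex is
#' `k_max * density(highest k-core)` of the subgraph induced by its closed
#' neighbourhood (the vertex plus its neighbours), where
#' `density = 2E/(V(V-1))`. A vertex whose neighbours share no edges has a
#' degenerate neighbourhood core and weight 0. In `"simple_clustering"` mode
#' the weight is the local clustering coefficient `C_i`
#' (see [local_clustering()]).
#'
#' @param graph an igraph object.
#' @param node vertex name or index.
#' @param mode `"core_density"` or `"simple_clustering"`.
#' @return A non-negative weight.
#' @export
vertex_weight <- function(graph, node, mode = c("core_density", "simple_clustering")) {
  mode <- match.arg(mode)
  if (is.character(node) && !(node %in% igraph::V(graph)$name)) {
    stop("unknown node: ", node)
  }
  if (mode == "simple_clustering") return(local_clustering(graph, node))
  nb <- igraph::neighbors(graph, node)
  if (length(nb) < 2) return(0)
  open_nb <- igraph::induced_subgraph(graph, nb)
  if (igraph::ecount(open_nb) == 0) return(0)
  closed <- igraph::induced_subgraph(graph, c(igraph::V(graph)[node], nb))
  core_no <- igraph::coreness(closed)
  k_max <- max(core_no)
  core <- igraph::induced_subgraph(closed, which(core_no >= k_max))
  # prune: coreness >= k_max does not by itself guarantee min degree k_max
  core <- k_core(core, k_max)
  k_max * graph_density(core)
}

#' @rdname vertex_weight
#' @return `mcode_weights()`: a named numeric vector of weights for every
#'   vertex.
#' @export
mcode_weights <- function(graph, mode = c("core_density", "simple_clustering")) {
  mode <- match.arg(mode)
  nm <- igraph::V(graph)$name
  if (is.null(nm)) {
    nm <- as.character(seq_len(igraph::vcount(graph)))
    igraph::V(graph)$name <- nm
  }
  setNames(vapply(nm, function(v) vertex_weight(graph, v, mode), 0), nm)
}

#' MCODE seed expansion
#'
#' Processes vertices as seeds in decreasing weight order (ties broken by
#' lexicographic vertex name, so runs are deterministic). From each unvisited
#' seed of positive weight, a breadth-first expansion includes an unvisited
#' neighbour `v` iff `weight(v) >= (1 - vwp) * weight(seed)` (inclusive),
#' up to `max_depth` BFS layers from the seed. Every vertex joins at most one
#' candidate cluster (visited-once rule).
#'
#' @param graph an igraph object with named vertices.
#' @param weights named weight vector from [mcode_weights()].
#' @param params an [mcode_params()] object.
#' @return A list of candidate clusters, each a list with `members` (character
#'   vector) and `seed`.
#' @export
mcode_find_clusters <- function(graph, weights, params = mcode_params()) {
  nm <- igraph::V(graph)$name
  stopifnot(!is.null(nm), all(nm %in% names(weights)))
  weights <- weights[nm]
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  adj <- lapply(adj, function(v) nm[as.integer(v)])
  names(adj) <- nm
  order_idx <- order(-weights, nm)
  visited <- setNames(rep(FALSE, length(nm)), nm)
  clusters <- list()
  for (seed in nm[order_idx]) {
    if (visited[[seed]] || weights[[seed]] <= 0) next
    threshold <- (1 - params$vwp) * weights[[seed]]
    members <- seed
    visited[[seed]] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- character(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (!visited[[v]] && weights[[v]] >= threshold) {
            visited[[v]] <- TRUE
            members <- c(members, v)
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    clusters[[length(clusters) + 1L]] <- list(members = members, seed = seed)
  }
  clusters
}

#' MCODE post-processing
#'
#' Applies the MCODE post-processing filters to candidate clusters: clusters
#' whose induced subgraph contains no `kcore_filter`-core are discarded; with
#' `haircut`, singly-connected members are removed iteratively (the cluster is
#' reduced to its 2-core); with `fluff`, boundary neighbours whose closed
#' neighbourhood density exceeds `fluff_density_cutoff` are added (fluffed
#' members may overlap between clusters, which is why fluff defaults to off).
#'
#' @param graph the full igraph object the clusters came from.
#' @param clusters candidate clusters from [mcode_find_clusters()].
#' @param params an [mcode_params()] object.
#' @return The filtered list of clusters (`members`, `seed`).
#' @export
mcode_post_process <- function(graph, clusters, params = mcode_params()) {
  out <- list()
  for (cl in clusters) {
    sub <- igraph::induced_subgraph(graph, cl$members)
    if (igraph::vcount(k_core(sub, params$kcore_filter)) == 0) next
    if (params$haircut) {
      sub <- k_core(sub, 2L)
      if (igraph::vcount(sub) == 0) next
      cl$members <- igraph::V(sub)$name
    }
    if (params$fluff) {
      boundary <- setdiff(
        unique(unlist(lapply(
          igraph::adjacent_vertices(graph, cl$members),
          function(v) igraph::V(graph)$name[as.integer(v)]))),
        cl$members)
      dens <- vapply(boundary, function(v) {
        nbv <- igraph::neighbors(graph, v)
        graph_density(igraph::induced_subgraph(graph, c(igraph::V(graph)[v], nbv)))
      }, 0)
      cl$members <- c(cl$members, boundary[dens > params$fluff_density_cutoff])
    }
    out[[length(out) + 1L]] <- cl
  }
  out
}

#' MCODE cluster score
#'
#' The score of a cluster is its density times its size,
#' `score = 2E/(V(V-1)) * V`, a measure of how large and dense the cluster is.
#' Single-vertex clusters score 0.
#'
#' @param graph the full igraph object.
#' @param cluster a cluster (list with `members`) or a character vector of
#'   member names.
#' @return The numeric score.
#' @export
score_cluster <- function(graph, cluster) {
  members <- if (is.list(cluster)) cluster$members else cluster
  if (!length(members)) stop("empty cluster")
  sub <- igraph::induced_subgraph(graph, members)
  graph_density(sub) * igraph::vcount(sub)
}

#' Run the full MCODE algorithm
#'
#' Vertex weighting ([mcode_weights()]), seed expansion
#' ([mcode_find_clusters()]), post-processing ([mcode_post_process()]) and
#' scoring ([score_cluster()]), returning clusters ranked by descending score
#' (ties broken by larger size, then by smallest member name, so output is
#' deterministic). Edge signs are ignored: MCODE clusters the unsigned
#' topology and sign structure is analysed downstream ([guild_report()]).
#'
#' @param graph an igraph object (vertex names are assigned from indices when
#'   missing).
#' @param params an [mcode_params()] object.
#' @return A list of clusters of class `mcode_cluster`, each with `members`,
#'   `n_edges`, `density`, `score`, `rank`, `seed`. Use
#'   [clusters_summary()] for a data.frame view.
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- letters[1:5]
#' run_mcode(g)[[1]]$score  # 5-clique scores 5
#' @export
run_mcode <- function(graph, params = mcode_params()) {
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  if (igraph::vcount(graph) == 0) return(list())
  w <- mcode_weights(graph, params$weight_mode)
  cand <- mcode_find_clusters(graph, w, params)
  cand <- mcode_post_process(graph, cand, params)
  if (!length(cand)) return(list())
  scored <- lapply(cand, function(cl) {
    sub <- igraph::induced_subgraph(graph, cl$members)
    list(members = sort(cl$members),
         n_edges = igraph::ecount(sub),
         density = graph_density(sub),
         score = graph_density(sub) * igraph::vcount(sub),
         seed = cl$seed)
  })
  ord <- order(-vapply(scored, `[[`, 0, "score"),
               -lengths(lapply(scored, `[[`, "members")),
               vapply(scored, function(cl) cl$members[1L], ""))
  scored <- scored[ord]
  for (i in seq_along(scored)) {
    scored[[i]]$rank <- i
    class(scored[[i]]) <- "mcode_cluster"
  }
  scored
}

#' Summarise MCODE clusters
#'
#' @param clusters list of clusters from [run_mcode()].
#' @return A data.frame with one row per cluster: `rank`, `score`, `n_nodes`,
#'   `n_edges`, `density`, `seed`.
#' @export
clusters_summary <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(rank = integer(), score = numeric(), n_nodes = integer(),
                      n_edges = integer(), density = numeric(),
                      seed = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    rank = vapply(clusters, `[[`, 0L, "rank"),
    score = vapply(clusters, `[[`, 0, "score"),
    n_nodes = lengths(lapply(clusters, `[[`, "members")),
    n_edges = vapply(clusters, function(cl) as.integer(cl$n_edges), 0L),
    density = vapply(clusters, `[[`, 0, "density"),
    seed = vapply(clusters, `[[`, "", "seed"),
    stringsAsFactors = FALSE)
}

#' Write cluster memberships to TSV
#'
#' One row per member node with columns
#' `cluster_id, node, score, rank`.
#'
#' @param clusters list of clusters from [run_mcode()].
#' @param path output file path.
#' @param digits significant digits for the score column.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path, digits = 6) {
  rows <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$rank, node = cl$members,
               score = signif(cl$score, digits), rank = cl$rank,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(cluster_id = integer(), node = character(),
                       score = numeric(), rank = integer())
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
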