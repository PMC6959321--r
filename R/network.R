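#' Filter low-abundance OTUs
#'
#' Removes OTUs whose total reads across all samples fall below `min_total`
#' (default 30, roughly one read per sample in a 29-sample study). This is the
#' standard de-noising step before correlation network construction: OTUs with
#' row sum `>= min_total` are retained, the sample set is unchanged.
#'
#' @param table an [otu_table()].
#' @param min_total non-negative integer threshold; rows with
#'   `rowSums(counts) < min_total` are dropped. `min_total = 0` is the
#'   identity.
#' @return The filtered [otu_table()]. An empty result triggers a warning,
#'   not an error.
#' @export
filter_low_abundance <- function(table, min_total = 30) {
  stopifnot(inherits(table, "otu_table"))
  if (length(min_total) != 1L || min_total < 0) stop("min_total must be >= 0")
  keep <- rowSums(unclass(table)) >= min_total
  if (!any(keep)) warning("all OTUs removed by abundance filter")
  out <- unclass(table)[keep, , drop = FALSE]
  class(out) <- c("otu_table", class(out))
  out
}

#' Build a signed Spearman co-occurrence network
#'
#' Tests every OTU pair with [spearman_matrix()] and keeps as edges the pairs
#' with `|R| >= r_min` and `p <= p_max` (both criteria inclusive; defaults
#' `r_min = 0.6`, `p_max = 0.05`). Each edge carries the coefficient `r`, its
#' `p_value`, and `sign` (`"positive"`/`"negative"` from the sign of `r`).
#' Nodes left without any qualifying edge are dropped when
#' `drop_isolated = TRUE` (default), which is why a filtered table of p OTUs
#' typically yields a network with fewer than p nodes.
#'
#' Raw p-values are used by default, matching common practice for fixed-|R|
#' thresholded networks; `bh_adjust = TRUE` applies a Benjamini-Hochberg
#' correction across all tested pairs before thresholding.
#'
#' @param table a filtered [otu_table()] with at least 2 OTUs.
#' @param r_min minimum absolute Spearman coefficient for an edge.
#' @param p_max maximum p-value for an edge.
#' @param drop_isolated drop degree-0 nodes from the returned graph.
#' @param bh_adjust apply Benjamini-Hochberg adjustment to the p-values first.
#' @return An undirected igraph object with edge attributes `r`, `p_value`,
#'   `sign`, and graph attributes recording the thresholds and skipped
#'   (constant) OTUs.
#' @export
build_network <- function(table, r_min = 0.6, p_max = 0.05,
                          drop_isolated = TRUE, bh_adjust = FALSE) {
  stopifnot(inherits(table, "otu_table"))
  if (nrow(table) < 2L) stop("need at least 2 OTUs to build a network")
  sm <- spearman_matrix(table)
  r <- sm$r
  p <- sm$p_value
  labels <- rownames(r)
  ut <- upper.tri(r)
  if (bh_adjust) p[ut] <- stats::p.adjust(p[ut], method = "BH")
  keep <- ut & abs(r) >= r_min & p <= p_max
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    from = labels[idx[, 1L]],
    to = labels[idx[, 2L]],
    r = r[keep],
    p_value = p[keep],
    stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = labels))
  if (drop_isolated) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  g <- igraph::set_graph_attr(g, "r_min", r_min)
  g <- igraph::set_graph_attr(g, "p_max", p_max)
  g <- igraph::set_graph_attr(g, "n_samples", sm$n)
  g <- igraph::set_graph_attr(g, "skipped_otus", paste(sm$skipped, collapse = ","))
  g
}

#' Local clustering coefficient
#'
#' `C_i = 2n / (k_i (k_i - 1))` where `k_i` is the degree of the node and `n`
#' the number of edges among its neighbours (edge signs ignored). Nodes with
#' `k_i < 2` have `C_i` defined as 0.
#'
#' @param net an igraph object.
#' @param node a vertex name or index present in `net`.
#' @return The clustering coefficient in \[0, 1\].
#' @export
local_clustering <- function(net, node) {
  if (is.character(node) && !(node %in% igraph::V(net)$name)) {
    stop("unknown node: ", node)
  }
  k <- unname(igraph::degree(net, node))
  if (k < 2) return(0)
  nb <- igraph::neighbors(net, node)
  sub <- igraph::induced_subgraph(net, nb)
  2 * igraph::ecount(sub) / (k * (k - 1))
}

#' Positive-to-negative link ratio
#'
#' The P/N ratio `n_positive / n_negative` measures the balance between
#' cooperative (positive) and competitive (negative) associations in a signed
#' network. With no negative links it is `Inf`; with no links at all it is
#' undefined and reported as `NA`.
#'
#' @param n_positive,n_negative non-negative edge counts.
#' @return A single number (possibly `Inf` or `NA`).
#' @examples
#' pn_ratio(3692, 643)  # 5.742 to three decimals
#' @export
pn_ratio <- function(n_positive, n_negative) {
  if (n_positive < 0 || n_negative < 0) stop("edge counts must be non-negative")
  if (n_negative == 0) {
    if (n_positive == 0) return(NA_real_)
    return(Inf)
  }
  n_positive / n_negative
}

#' Whole-network topology statistics
#'
#' Computes the standard descriptive statistics of a signed co-occurrence
#' network: node and edge counts, positive/negative edge counts and their P/N
#' ratio, average degree `2E/V`, mean local clustering coefficient (signs
#' ignored, `C_i = 0` for degree < 2), diameter and average path length
#' (computed on the largest connected component when the graph is
#' disconnected; the component count is reported alongside so the convention
#' is visible), density `2E/(V(V-1))`, and modularity / community count from a
#' sign-blind community detection on the unsigned topology
#' (`"greedy_modularity"`, the default, uses fast greedy modularity
#' maximisation; `"louvain"` is also available). The method used is recorded
#' in the output.
#'
#' @param net an igraph object with a `sign` edge attribute (edges without the
#'   attribute are treated as positive).
#' @param community_method `"greedy_modularity"` (default) or `"louvain"`.
#' @return A list of class `network_stats`.
#' @export
network_stats <- function(net, community_method = c("greedy_modularity", "louvain")) {
  community_method <- match.arg(community_method)
  nv <- igraph::vcount(net)
  ne <- igraph::ecount(net)
  if (nv == 0) stop("empty network")
  signs <- igraph::E(net)$sign
  if (is.null(signs)) signs <- rep("positive", ne)
  n_pos <- sum(signs == "positive")
  n_neg <- sum(signs == "negative")
  local_cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  local_cc[is.na(local_cc)] <- 0
  comp <- igraph::components(net)
  giant <- igraph::induced_subgraph(net, which(comp$membership ==
                                                 which.max(comp$csize)))
  comm <- switch(community_method,
    greedy_modularity = igraph::cluster_fast_greedy(igraph::simplify(net)),
    louvain = igraph::cluster_louvain(igraph::simplify(net)))
  structure(list(
    n_nodes = nv,
    n_edges = ne,
    n_positive = n_pos,
    n_negative = n_neg,
    pn_ratio = pn_ratio(n_pos, n_neg),
    average_degree = 2 * ne / nv,
    average_local_clustering = mean(local_cc),
    diameter = igraph::diameter(giant, weights = NA),
    average_path_length = igraph::mean_distance(giant),
    n_components = comp$no,
    density = if (nv > 1) 2 * ne / (nv * (nv - 1)) else 0,
    modularity = igraph::modularity(comm),
    n_communities = length(comm),
    community_method = community_method
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("network_stats\n")
  for (f in setdiff(names(x), "community_method")) {
    cat(sprintf("  %-26s %s\n", f, format(x[[f]], digits = 6)))
  }
  cat(sprintf("  %-26s %s\n", "community_method", x$community_method))
  invisible(x)
}

#' Export a signed network
#'
#' `write_edge_list()` writes a TSV with columns
#' `source, target, r, p_value, sign`; `write_network_graphml()` writes
#' GraphML with the same attributes (via [igraph::write_graph()]).
#'
#' @param net an igraph object with `r`, `p_value`, `sign` edge attributes.
#' @param path output file path.
#' @param digits significant digits for floating-point columns in the TSV.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, digits = 6) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(source = el[, 1L], target = el[, 2L],
                   r = signif(igraph::E(net)$r, digits),
                   p_value = signif(igraph::E(net)$p_value, digits),
                   sign = igraph::E(net)$sign,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
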