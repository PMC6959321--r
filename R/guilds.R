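#' Partition a signed cluster into sub-guilds
#'
#' Sub-guilds are the sign-coherent subgroups of a guild: within a sub-guild
#' all associations are cooperative (positive), between sub-guilds they are
#' competitive (negative). The partition is derived from the data rather than
#' assumed: endpoints of every positive edge are merged (union-find), so the
#' groups are the connected components of the positive-edge subgraph
#' (vertices with no positive edges form singletons). Any negative edge that
#' ends up inside a group violates the sign pattern and is recorded as
#' frustrated; the partition is `balanced` iff no edge is frustrated. The
#' number of groups is an emergent result, not fixed at two.
#'
#' @param cluster_subgraph an igraph object with a `sign` edge attribute.
#' @return A list of class `subguild_partition` with `groups` (list of member
#'   vectors, ordered by decreasing size), `membership` (named integer vector
#'   of group indices), `frustrated_edges` (data.frame `from`, `to`, `sign`),
#'   and `balanced`.
#' @export
partition_subguilds <- function(cluster_subgraph) {
  g <- cluster_subgraph
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  nm <- igraph::V(g)$name
  signs <- edge_signs(g)
  pos <- igraph::subgraph_from_edges(g, igraph::E(g)[signs == "positive"],
                                     delete.vertices = FALSE)
  comp <- igraph::components(pos)
  membership <- setNames(comp$membership, nm)
  # relabel groups by decreasing size, ties by smallest member name
  groups <- split(nm, membership)
  ord <- order(-lengths(groups), vapply(groups, function(x) sort(x)[1L], ""))
  groups <- lapply(groups[ord], sort)
  membership <- setNames(rep(seq_along(groups), lengths(groups)),
                         unlist(groups))[nm]
  names(membership) <- nm
  el <- igraph::as_edgelist(g)
  frustrated <- (signs == "negative" & membership[el[, 1L]] == membership[el[, 2L]]) |
    (signs == "positive" & membership[el[, 1L]] != membership[el[, 2L]])
  structure(list(
    groups = unname(groups),
    membership = membership,
    frustrated_edges = data.frame(from = el[frustrated, 1L],
                                  to = el[frustrated, 2L],
                                  sign = signs[frustrated],
                                  stringsAsFactors = FALSE),
    balanced = !any(frustrated)
  ), class = "subguild_partition")
}

edge_signs <- function(g) {
  signs <- igraph::E(g)$sign
  if (is.null(signs)) {
    r <- igraph::E(g)$r
    if (is.null(r)) stop("graph has neither 'sign' nor 'r' edge attribute")
    signs <- ifelse(r >= 0, "positive", "negative")
  }
  signs
}

#' Classify cluster nodes as guard, civilian, or anomalous
#'
#' A *guard* node of a sub-guild holds at least one negative association with
#' another sub-guild while all its within-sub-guild associations are positive;
#' a *civilian* node holds no negative association at all; a node with a
#' negative association inside its own sub-guild contradicts the sub-guild
#' sign pattern and is flagged *anomalous*. The three classes partition the
#' cluster's nodes, and on a balanced partition no node is anomalous.
#'
#' @param cluster_subgraph an igraph object with a `sign` edge attribute.
#' @param partition a [partition_subguilds()] result for the same graph (the
#'   partition may also come from external annotation, e.g. the packaged
#'   guild fixture).
#' @return A data.frame with columns `node`, `sub_guild` (group index), and
#'   `role`.
#' @export
classify_roles <- function(cluster_subgraph, partition) {
  g <- cluster_subgraph
  nm <- igraph::V(g)$name
  membership <- partition$membership[nm]
  if (anyNA(membership)) stop("partition does not cover all graph vertices")
  signs <- edge_signs(g)
  el <- igraph::as_edgelist(g)
  neg <- signs == "negative"
  neg_within <- neg & membership[el[, 1L]] == membership[el[, 2L]]
  neg_cross <- neg & !neg_within
  has_neg_within <- nm %in% c(el[neg_within, 1L], el[neg_within, 2L])
  has_neg_cross <- nm %in% c(el[neg_cross, 1L], el[neg_cross, 2L])
  role <- ifelse(has_neg_within, "anomalous",
                 ifelse(has_neg_cross, "guard", "civilian"))
  data.frame(node = nm, sub_guild = unname(membership), role = role,
             stringsAsFactors = FALSE)
}

# round half away from zero, as printed summary tables conventionally do
round_half_up <- function(x, digits = 1) {
  floor(abs(x) * 10^digits + 0.5) / 10^digits * sign(x)
}

#' Phylum composition of a cluster
#'
#' Counts cluster members per phylum group (the three focal phyla
#' Actinobacteria, Firmicutes and Bacteroidetes; everything else, including
#' unmapped taxa, pooled as "Others") with percentages of the cluster size
#' rounded half-up to one decimal.
#'
#' @param members character vector of member OTU labels.
#' @param taxonomy named character vector mapping each member to a phylum
#'   (e.g. from [lookup_phylum()] or the `phylum_group` column of
#'   [load_fba_roles()]). Defaults to label-based lookup in the packaged map.
#' @return A data.frame with columns `phylum`, `n`, `percent`, ordered
#'   Actinobacteria, Firmicutes, Bacteroidetes, Others (empty input gives an
#'   empty data.frame).
#' @export
phylum_composition <- function(members, taxonomy = lookup_phylum(members)) {
  lev <- c("Actinobacteria", "Firmicutes", "Bacteroidetes", "Others")
  if (!length(members)) {
    return(data.frame(phylum = character(), n = integer(), percent = numeric(),
                      stringsAsFactors = FALSE))
  }
  ph <- collapse_phylum_group(unname(taxonomy[members]))
  counts <- table(factor(ph, levels = lev))
  data.frame(phylum = lev, n = as.integer(counts),
             percent = round_half_up(100 * as.integer(counts) / length(members), 1),
             stringsAsFactors = FALSE)
}

#' Phylum-pair interaction summary
#'
#' For each unordered pair of phylum groups, counts the positive and negative
#' edges with one endpoint in each phylum and computes their P/N ratio
#' ([pn_ratio()]). Edges whose endpoints share a phylum are diagonal entries
#' `(phylum, phylum)`; they are excluded from the inter-phylum comparison by
#' default.
#'
#' @param cluster_subgraph an igraph object with a `sign` edge attribute.
#' @param taxonomy named character vector mapping each vertex to a phylum.
#' @param include_within also report same-phylum (diagonal) pairs.
#' @return A data.frame with columns `phylum_a`, `phylum_b`, `n_total`,
#'   `n_positive`, `n_negative`, `pn_ratio`.
#' @export
phylum_pair_summary <- function(cluster_subgraph,
                                taxonomy = lookup_phylum(igraph::V(cluster_subgraph)$name),
                                include_within = FALSE) {
  g <- cluster_subgraph
  nm <- igraph::V(g)$name
  ph <- collapse_phylum_group(unname(taxonomy[nm]))
  names(ph) <- nm
  signs <- edge_signs(g)
  el <- igraph::as_edgelist(g)
  if (!nrow(el)) {
    return(data.frame(phylum_a = character(), phylum_b = character(),
                      n_total = integer(), n_positive = integer(),
                      n_negative = integer(), pn_ratio = numeric(),
                      stringsAsFactors = FALSE))
  }
  pa <- pmin(ph[el[, 1L]], ph[el[, 2L]])
  pb <- pmax(ph[el[, 1L]], ph[el[, 2L]])
  key <- paste(pa, pb, sep = "\r")
  keys <- sort(unique(key))
  rows <- lapply(keys, function(k) {
    sel <- key == k
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    npos <- sum(signs[sel] == "positive")
    nneg <- sum(signs[sel] == "negative")
    data.frame(phylum_a = parts[1L], phylum_b = parts[2L],
               n_total = npos + nneg, n_positive = npos, n_negative = nneg,
               pn_ratio = pn_ratio(npos, nneg), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!include_within) out <- out[out$phylum_a != out$phylum_b, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full guild report for one cluster
#'
#' Bundles the sub-guild partition, guard/civilian/anomalous roles, phylum
#' composition (overall and per sub-guild), the dominant phylum of each
#' sub-guild (all tied phyla reported and flagged when the maximum is not
#' unique), and the phylum-pair P/N summary, for the subgraph of `network`
#' induced by the cluster's members.
#'
#' @param network a signed igraph object (e.g. from [build_network()]).
#' @param cluster an `mcode_cluster` from [run_mcode()], or a character vector
#'   of member names.
#' @param taxonomy named character vector mapping members to phyla; defaults
#'   to label-based lookup in the packaged map.
#' @return A list of class `guild_report` with elements `members`,
#'   `partition`, `roles`, `composition`, `group_composition`,
#'   `dominant_phylum`, `guard_counts`, `pair_summary`. Serialise with
#'   [write_guild_report()].
#' @export
guild_report <- function(network, cluster, taxonomy = NULL) {
  members <- if (is.list(cluster)) cluster$members else cluster
  if (!length(members)) stop("empty cluster")
  if (is.null(taxonomy)) taxonomy <- lookup_phylum(members)
  sub <- igraph::induced_subgraph(network, members)
  part <- partition_subguilds(sub)
  roles <- classify_roles(sub, part)
  roles$phylum <- collapse_phylum_group(unname(taxonomy[roles$node]))
  group_comp <- lapply(part$groups, function(gm) phylum_composition(gm, taxonomy))
  dominant <- lapply(seq_along(part$groups), function(i) {
    comp <- group_comp[[i]]
    mx <- max(comp$n)
    tied <- comp$phylum[comp$n == mx]
    list(group = i, phylum = tied, fraction = mx / length(part$groups[[i]]),
         tie = length(tied) > 1L)
  })
  guard_counts <- vapply(seq_along(part$groups), function(i) {
    sum(roles$role == "guard" & roles$sub_guild == i)
  }, 0L)
  structure(list(
    members = sort(members),
    partition = part,
    roles = roles,
    composition = phylum_composition(members, taxonomy),
    group_composition = group_comp,
    dominant_phylum = dominant,
    guard_counts = guard_counts,
    pair_summary = phylum_pair_summary(sub, taxonomy)
  ), class = "guild_report")
}

#' @export
print.guild_report <- function(x, ...) {
  cat(sprintf("guild_report: %d members, %d sub-guild(s), %s\n",
              length(x$members), length(x$partition$groups),
              if (x$partition$balanced) "balanced" else
                sprintf("%d frustrated edge(s)", nrow(x$partition$frustrated_edges))))
  for (d in x$dominant_phylum) {
    cat(sprintf("  sub-guild %d: %d nodes, %d guard(s), dominant %s (%.1f%%)%s\n",
                d$group, length(x$partition$groups[[d$group]]),
                x$guard_counts[d$group], paste(d$phylum, collapse = "/"),
                100 * d$fraction, if (d$tie) " [tie]" else ""))
  }
  invisible(x)
}

#' Serialise a guild report
#'
#' `write_guild_report()` writes the full report as JSON;
#' `write_node_roles()` writes the per-node table as TSV with columns
#' `node, sub_guild, role, phylum`.
#'
#' @param report a [guild_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_guild_report <- function(report, path) {
  x <- report
  x$partition <- list(groups = x$partition$groups,
                      frustrated_edges = x$partition$frustrated_edges,
                      balanced = x$partition$balanced)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = 6,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_guild_report
#' @export
write_node_roles <- function(report, path) {
  write.table(report$roles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
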