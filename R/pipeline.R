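#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis (abundance filter,
#' edge criteria, community method, MCODE parameters, phylum map, which
#' cluster to analyse, and the seed) into one serializable object, so a run
#' can be reproduced from its manifest alone.
#'
#' @param min_total abundance filter threshold (see [filter_low_abundance()]).
#' @param r_min,p_max edge criteria (see [build_network()]).
#' @param drop_isolated drop degree-0 nodes from the network.
#' @param bh_adjust Benjamini-Hochberg adjust p-values before thresholding.
#' @param community_method community detection for [network_stats()].
#' @param mcode an [mcode_params()] object.
#' @param phylum_map optional path to a phylum map TSV; `NULL` uses the
#'   packaged default.
#' @param cluster_rank which ranked cluster the guild analysis targets.
#' @param seed integer seed recorded in outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_total = 30, r_min = 0.6, p_max = 0.05,
                            drop_isolated = TRUE, bh_adjust = FALSE,
                            community_method = "greedy_modularity",
                            mcode = mcode_params(), phylum_map = NULL,
                            cluster_rank = 1L, seed = 1L) {
  if (!inherits(mcode, "mcode_params")) mcode <- do.call(mcode_params, mcode)
  structure(list(min_total = min_total, r_min = r_min, p_max = p_max,
                 drop_isolated = drop_isolated, bh_adjust = bh_adjust,
                 community_method = community_method, mcode = mcode,
                 phylum_map = phylum_map, cluster_rank = as.integer(cluster_rank),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path file path for YAML serialisation.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$mcode <- unclass(x$mcode)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$mcode)) vals$mcode <- do.call(mcode_params, vals$mcode)
  do.call(pipeline_config, vals)
}

#' Run the full guild-detection pipeline
#'
#' Chains [filter_low_abundance()], [build_network()], [network_stats()],
#' [run_mcode()], and [guild_report()] on the cluster selected by
#' `config$cluster_rank`, logging OTU/node/edge counts at each stage.
#' An empty network after thresholding is an error of class
#' `guildnet_empty_network` (the command-line wrapper maps it to exit
#' status 3).
#'
#' @param table an [otu_table()] or a path to an OTU table TSV.
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return A list of class `pipeline_result` with `config`, `counts` (stage
#'   count log), `filtered` table, `network`, `stats`, `clusters`, `report`
#'   (NULL when fewer clusters than `cluster_rank` were found).
#' @export
run_pipeline <- function(table, config = pipeline_config(), quiet = FALSE) {
  if (is.character(table)) table <- read_otu_table(table)
  stopifnot(inherits(table, "otu_table"), inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  counts <- list(otus_in = nrow(table), samples = ncol(table))
  say("input: %d OTUs x %d samples", nrow(table), ncol(table))
  filtered <- filter_low_abundance(table, config$min_total)
  counts$otus_after_filter <- nrow(filtered)
  say("after abundance filter (>= %g total reads): %d OTUs",
      config$min_total, nrow(filtered))
  net <- build_network(filtered, r_min = config$r_min, p_max = config$p_max,
                       drop_isolated = config$drop_isolated,
                       bh_adjust = config$bh_adjust)
  if (igraph::ecount(net) == 0) {
    stop(structure(class = c("guildnet_empty_network", "error", "condition"),
                   list(message = sprintf(
                     "no edges satisfy |R| >= %g and p <= %g",
                     config$r_min, config$p_max), call = NULL)))
  }
  signs <- igraph::E(net)$sign
  counts$nodes <- igraph::vcount(net)
  counts$edges <- igraph::ecount(net)
  counts$positive_edges <- sum(signs == "positive")
  counts$negative_edges <- sum(signs == "negative")
  say("network: %d nodes, %d edges (%d positive / %d negative)",
      counts$nodes, counts$edges, counts$positive_edges, counts$negative_edges)
  stats <- network_stats(net, community_method = config$community_method)
  clusters <- run_mcode(net, config$mcode)
  counts$clusters <- length(clusters)
  say("MCODE: %d cluster(s)", length(clusters))
  taxonomy_map <- if (is.null(config$phylum_map)) default_phylum_map() else
    load_phylum_map(config$phylum_map)
  report <- NULL
  if (length(clusters) >= config$cluster_rank) {
    cl <- clusters[[config$cluster_rank]]
    report <- guild_report(net, cl,
                           taxonomy = lookup_phylum(cl$members, taxonomy_map))
    say("guild analysis of cluster %d: %d members, %d sub-guild(s), %d guard(s)",
        config$cluster_rank, length(cl$members),
        length(report$partition$groups), sum(report$guard_counts))
  } else {
    say("cluster rank %d not available; guild analysis skipped",
        config$cluster_rank)
  }
  structure(list(config = config, counts = counts, filtered = filtered,
                 network = net, stats = stats, clusters = clusters,
                 report = report),
            class = "pipeline_result")
}

#' Write pipeline outputs and a manifest
#'
#' Writes the edge list (TSV), the network (GraphML), the network statistics
#' (JSON), cluster memberships (TSV), the guild report (JSON) and node role
#' table (TSV) when present, plus `manifest.json` recording the configuration
#' verbatim with an MD5 hash, the package version, stage counts, and the file
#' list. Floating-point columns are serialised at 6 significant digits so
#' reruns are byte-reproducible.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- function(f) file.path(dir, f)
  write_edge_list(result$network, p("edges.tsv"))
  write_network_graphml(result$network, p("network.graphml"))
  jsonlite::write_json(unclass(result$stats), p("network_stats.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  write_clusters(result$clusters, p("clusters.tsv"))
  files <- c("edges.tsv", "network.graphml", "network_stats.json", "clusters.tsv")
  if (!is.null(result$report)) {
    write_guild_report(result$report, p("guild_report.json"))
    write_node_roles(result$report, p("node_roles.tsv"))
    files <- c(files, "guild_report.json", "node_roles.tsv")
  }
  cfg_path <- p("config.yaml")
  write_pipeline_config(result$config, cfg_path)
  files <- c(files, "config.yaml")
  manifest <- list(
    package = "guildnet",
    version = as.character(utils::packageVersion("guildnet")),
    config = yaml::read_yaml(cfg_path),
    config_md5 = unname(tools::md5sum(cfg_path)),
    stage_counts = result$counts,
    files = files)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = 6, pretty = TRUE)
  invisible(p("manifest.json"))
}

#' Simulate a table and write table, ground truth, spec, and manifest
#'
#' Thin orchestration over [simulate_counts()]: writes `table.tsv`,
#' `ground_truth.json` (assignments only; the latent matrix is reproducible
#' from the spec), `spec.yaml`, and `manifest.json` listing the files.
#'
#' @param spec a [simulation_spec()] or path to a spec YAML.
#' @param dir output directory (created if needed).
#' @return The list of written paths, invisibly.
#' @export
run_simulation <- function(spec, dir) {
  if (is.character(spec)) spec <- read_simulation_spec(spec)
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_counts(spec)
  p <- function(f) file.path(dir, f)
  write_otu_table(sim$table, p("table.tsv"))
  jsonlite::write_json(sim$truth$assignments, p("ground_truth.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  write_simulation_spec(spec, p("spec.yaml"))
  manifest <- list(package = "guildnet",
                   version = as.character(utils::packageVersion("guildnet")),
                   seed = spec$seed,
                   files = c("table.tsv", "ground_truth.json", "spec.yaml"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(vapply(c("table.tsv", "ground_truth.json", "spec.yaml",
                     "manifest.json"), p, ""))
}
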