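#' Reference annotation of the FBA oral-microbiome guild
#'
#' `load_fba_roles()` returns the packaged 55-node reference annotation of the
#' strongest cluster ("FBA guild") of a healthy oral-microbiome co-occurrence
#' network: for every member OTU its sub-guild (`ASG`, the
#' Actinobacteria-dominant sub-guild, or `FBSG`, the Firmicutes-dominant
#' sub-guild allied with Bacteroidetes), its role (`guard` or `civilian`), and
#' its phylum group (Actinobacteria / Firmicutes / Bacteroidetes / Others).
#' Rows whose phylum placement was typographically ambiguous in the source
#' layout are flagged in `layout_ambiguous`.
#'
#' `load_fba_negative_edges()` returns the 39 negative inter-sub-guild
#' correlations of the same guild, each with its Spearman coefficient
#' (all `r <= -0.6`), the printed p-value bound (`p_value`, with the verbatim
#' rendering in `p_printed`), and the phylum group on either side. All
#' endpoints of these edges are guard nodes.
#'
#' These tables serve as ground truth for classification tests and as a worked
#' example of the guild analysis.
#'
#' @return `load_fba_roles()`: a data.frame with columns `node`, `sub_guild`,
#'   `role`, `phylum_group`, `layout_ambiguous` (55 rows).
#' @examples
#' roles <- load_fba_roles()
#' table(roles$sub_guild, roles$role)
#' @export
load_fba_roles <- function() {
  path <- system.file("extdata", "fba_guild_nodes.tsv", package = "guildnet",
                      mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$layout_ambiguous <- as.logical(df$layout_ambiguous)
  df
}

#' @rdname load_fba_roles
#' @return `load_fba_negative_edges()`: a data.frame with columns `asg_node`,
#'   `fbsg_node`, `r`, `p_value`, `p_printed`, `phylum_asg`, `phylum_fbsg`
#'   (39 rows).
#' @export
load_fba_negative_edges <- function() {
  path <- system.file("extdata", "fba_negative_edges.tsv", package = "guildnet",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Signed graph of the FBA guild reference fixture
#'
#' Builds an [igraph][igraph::igraph-package] graph over the 55 annotated guild
#' members carrying the 39 negative inter-sub-guild edges (edge attributes
#' `r`, `p_value`, and `sign = "negative"`). Positive within-sub-guild edges
#' are not part of the reference annotation, so civilians appear as isolated
#' vertices; the vertex attributes `sub_guild`, `role`, and `phylum_group`
#' carry the annotation.
#'
#' @return An igraph object with 55 vertices and 39 signed edges.
#' @export
fba_guild_graph <- function() {
  roles <- load_fba_roles()
  edges <- load_fba_negative_edges()
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$asg_node, to = edges$fbsg_node,
               r = edges$r, p_value = edges$p_value,
               sign = "negative", stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = roles$node, sub_guild = roles$sub_guild,
                          role = roles$role, phylum_group = roles$phylum_group,
                          stringsAsFactors = FALSE))
  g
}
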