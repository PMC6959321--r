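#' Parse an OTU label into its taxon name and number
#'
#' OTU labels follow the convention `<lowest annotated taxonomic level>_<id>`,
#' e.g. `"Corynebacterium_767"` or `"pallens_179"`. The label is split on the
#' LAST underscore so that the rule stays deterministic even if a taxon name
#' itself contained an underscore; the suffix must be an integer.
#'
#' @param label a single non-empty OTU label.
#' @return A list with `label`, `lowest_level_name`, and `otu_number`.
#' @examples
#' parse_taxon_label("Corynebacterium_767")
#' @export
parse_taxon_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("label must be a single non-empty string")
  }
  pos <- regexpr("_[^_]*$", label)
  if (pos < 1L) stop("parse error: no underscore in label '", label, "'")
  name <- substr(label, 1L, pos - 1L)
  suffix <- substr(label, pos + 1L, nchar(label))
  if (!nzchar(name)) stop("parse error: empty taxon name in '", label, "'")
  if (!grepl("^[0-9]+$", suffix)) {
    stop("parse error: non-numeric suffix in label '", label, "'")
  }
  list(label = label, lowest_level_name = name, otu_number = as.integer(suffix))
}

#' Load a taxon-name to phylum lookup table
#'
#' Reads a two-column TSV (`name`, `phylum`) into a named character vector.
#' Names absent from the table resolve to `"UNKNOWN"` via [lookup_phylum()].
#' Duplicate keys with conflicting phyla are a format error; consistent
#' duplicates are collapsed.
#'
#' @param path path to a two-column TSV. A header row is optional.
#' @return Named character vector mapping taxon name to phylum.
#' @export
load_phylum_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2L) stop("format error: phylum map must have exactly 2 columns")
  if (identical(tolower(df[1, 1]), "name")) df <- df[-1, , drop = FALSE]
  key <- as.character(df[[1]])
  val <- as.character(df[[2]])
  for (k in unique(key[duplicated(key)])) {
    if (length(unique(val[key == k])) > 1L) {
      stop("format error: conflicting phylum entries for '", k, "'")
    }
  }
  keep <- !duplicated(key)
  setNames(val[keep], key[keep])
}

#' Default phylum map packaged with guildnet
#'
#' Covers every taxon name appearing in the packaged FBA guild fixtures
#' (oral genera and family/order level names), mapping them to
#' Actinobacteria, Firmicutes, Bacteroidetes, Proteobacteria, Fusobacteria,
#' or `"Others"` for labels with no phylum-level annotation.
#'
#' @return Named character vector, as from [load_phylum_map()].
#' @export
default_phylum_map <- function() {
  load_phylum_map(system.file("extdata", "phylum_map.tsv", package = "guildnet",
                              mustWork = TRUE))
}

#' Resolve OTU labels to phyla
#'
#' Parses each label with [parse_taxon_label()] and looks the taxon name up in
#' `map`; unmapped names give `"UNKNOWN"`.
#'
#' @param labels character vector of OTU labels.
#' @param map named character vector from [load_phylum_map()]; defaults to the
#'   packaged map.
#' @return Character vector of phyla, named by label.
#' @export
lookup_phylum <- function(labels, map = default_phylum_map()) {
  names_lv <- vapply(labels, function(l) parse_taxon_label(l)$lowest_level_name, "")
  out <- unname(map[names_lv])
  out[is.na(out)] <- "UNKNOWN"
  setNames(out, labels)
}

# Collapse phyla to the guild reporting groups: the three focal phyla are kept,
# everything else (including UNKNOWN) is pooled as "Others".
collapse_phylum_group <- function(phyla,
                                  keep = c("Actinobacteria", "Firmicutes",
                                           "Bacteroidetes")) {
  ifelse(phyla %in% keep, phyla, "Others")
}
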