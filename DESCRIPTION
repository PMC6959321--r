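Package: guildnet
Title: Co-Occurrence Networks and Ecological Guild Analysis for Microbiome Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds signed Spearman co-occurrence networks from OTU abundance
    tables (rank correlation with |R| and p-value edge criteria, low-abundance
    filtering), detects dense network clusters with a from-scratch
    implementation of the MCODE algorithm (k-core based vertex weighting, seed
    expansion, haircut/fluff post-processing), and analyses detected clusters
    as ecological guilds: sign-based sub-guild partitioning, guard/civilian
    node classification, phylum composition and phylum-pair positive-to-negative
    link ratios. Includes a Gaussian-copula negative-binomial simulator that
    plants guild structure in synthetic count tables with recorded ground
    truth, plus a small command-line pipeline front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
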