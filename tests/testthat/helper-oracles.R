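# Shared fixtures and independent oracles used across the suite.

# named undirected graph from an edge data.frame (from, to, optional sign/r)
graph_from_edges <- function(edges, vertices = NULL) {
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

signed_edges <- function(...) {
  # signed_edges("a+b", "a-c") -> data.frame with sign parsed from the glyph
  specs <- c(...)
  from <- sub("[+-].*$", "", specs)
  to <- sub("^[^+-]*[+-]", "", specs)
  sgn <- ifelse(grepl("+", specs, fixed = TRUE), "positive", "negative")
  data.frame(from = from, to = to, sign = sgn,
             r = ifelse(sgn == "positive", 0.8, -0.8),
             stringsAsFactors = FALSE)
}

named_clique <- function(n, prefix = "v") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

# Brute-force Spearman oracle: explicit mid-ranking, then the Pearson
# product-moment formula written out longhand. Kept deliberately independent
# of rank()/cor() in the implementation path.
oracle_midrank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    # average of the positions the tied run occupies
    r[i] <- less + (ties + 1) / 2
  }
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x)
  ry <- oracle_midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Brute-force minimum frustration over every set partition (Bell-number
# enumeration; only usable for small vertex sets). An edge is frustrated when
# it is negative within a group or positive between groups.
oracle_min_frustration <- function(edges, vertices) {
  n <- length(vertices)
  assignments <- list(rep(1L, 1L))
  # enumerate restricted growth strings
  grow <- function(prefix) {
    if (length(prefix) == n) return(list(prefix))
    mx <- max(prefix)
    out <- list()
    for (k in seq_len(mx + 1L)) out <- c(out, grow(c(prefix, k)))
    out
  }
  parts <- grow(1L)
  frustration <- function(assign) {
    names(assign) <- vertices
    same <- assign[edges$from] == assign[edges$to]
    sum((edges$sign == "negative" & same) | (edges$sign == "positive" & !same))
  }
  min(vapply(parts, frustration, 0L))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
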