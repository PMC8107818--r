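# Network stage: bipartite compound-target graph, scored PPI edge lists
# (STRING-export style), score-threshold filtering, degree/betweenness
# topology, and the mean-degree hub rule. Graphs are undirected igraph
# objects; a `score` edge attribute carries interaction confidence and a
# `kind` vertex attribute ("compound"/"target") marks the bipartition.

#' Read a compound-to-target mapping
#'
#' @param path TSV with header `compound_id`, `target_symbol`.
#' @return `data.frame` of distinct edges, symbols upper-cased.
#' @export
read_compound_target_map <- function(path) {
  df <- read_delim_table(path, "tab")
  require_columns(df, c("compound_id", "target_symbol"), path)
  normalize_target_map(df)
}

#' Build the bipartite compound-target network
#'
#' One node per compound and per (optionally filtered) target, one
#' undirected edge per mapped pair. Compounds left isolated by target
#' filtering stay in the graph; targets only enter through an edge.
#'
#' @param mapping Edge `data.frame` from [read_compound_target_map()].
#' @param keep_targets Optional [target_set()]; edges to targets outside it
#'   are dropped (the drug-on-disease restriction).
#' @return An undirected `igraph` with vertex attribute `kind`.
#' @export
build_compound_target_network <- function(mapping, keep_targets = NULL) {
  mapping <- normalize_target_map(mapping)
  compounds <- unique(mapping$compound_id)
  if (!is.null(keep_targets)) {
    stopifnot(inherits(keep_targets, "target_set"))
    mapping <- mapping[mapping$target_symbol %in% keep_targets$symbols, ,
                       drop = FALSE]
  }
  targets <- sort_c(unique(mapping$target_symbol))
  overlap <- intersect(compounds, targets)
  if (length(overlap)) {
    stop_validation(sprintf("identifier(s) used as both compound and target: %s",
                            paste(overlap, collapse = ", ")))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(compounds), name = compounds,
                            kind = "compound")
  if (length(targets)) {
    g <- igraph::add_vertices(g, length(targets), name = targets,
                              kind = "target")
  }
  if (nrow(mapping)) {
    g <- igraph::add_edges(g, rbind(mapping$compound_id, mapping$target_symbol))
  }
  message(sprintf("compound-target network: %d nodes (%d compounds, %d targets), %d edges",
                  igraph::vcount(g), length(compounds), length(targets),
                  igraph::ecount(g)))
  g
}

#' Read a scored PPI edge list
#'
#' Accepts either the package's own header (`node_a`, `node_b`, `score`) or
#' a STRING export (`node1`, `node2`, `combined_score`). Scores on the
#' STRING 0-999 integer scale are auto-detected (any score above 1) and
#' divided by 1000 onto \[0, 1\]. Self-loops are dropped; duplicate edges
#' collapse to one, keeping the maximum score.
#'
#' @param path Path to the edge list (TSV).
#' @return Undirected `igraph` with a numeric `score` edge attribute.
#' @export
read_ppi_edges <- function(path) {
  df <- read_delim_table(path, "auto")
  if (all(c("node1", "node2") %in% names(df))) {
    names(df)[match(c("node1", "node2"), names(df))] <- c("node_a", "node_b")
  }
  if ("combined_score" %in% names(df) && !("score" %in% names(df))) {
    names(df)[names(df) == "combined_score"] <- "score"
  }
  require_columns(df, c("node_a", "node_b"), path)
  a <- toupper(trimws(df$node_a))
  b <- toupper(trimws(df$node_b))
  score <- if ("score" %in% names(df)) as_real(df$score, "score") else
    rep(NA_real_, nrow(df))
  if (any(!is.na(score)) && max(score, na.rm = TRUE) > 1) score <- score / 1000
  if (any(!is.na(score) & (score < 0 | score > 1))) {
    stop_validation("PPI scores must normalise into [0, 1]")
  }
  keep <- a != b
  edges <- data.frame(a = a[keep], b = b[keep], score = score[keep],
                      stringsAsFactors = FALSE)
  # canonical endpoint order, then collapse duplicates keeping max score
  flip <- edges$a > edges$b
  tmp <- edges$a[flip]; edges$a[flip] <- edges$b[flip]; edges$b[flip] <- tmp
  key <- paste(edges$a, edges$b, sep = "\r")
  if (anyDuplicated(key)) {
    mx <- tapply(edges$score, key, function(s) if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE))
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$score <- as.numeric(mx[paste(edges$a, edges$b, sep = "\r")])
  }
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  igraph::E(g)$score <- edges$score
  g
}

#' Filter network edges by interaction score
#'
#' Keeps edges whose confidence score is at least `min_score` (inclusive,
#' matching STRING's "lowest interaction score" semantics) and drops nodes
#' the filter leaves isolated. The default threshold 0.400 is STRING's
#' medium-confidence cut.
#'
#' @param network `igraph` with a `score` edge attribute.
#' @param min_score Minimum score retained; default 0.400.
#' @param inclusive Keep edges equal to the threshold (default `TRUE`).
#' @return The filtered `igraph`.
#' @export
filter_edges_by_score <- function(network, min_score = 0.400, inclusive = TRUE) {
  score <- igraph::E(network)$score
  if (is.null(score) || anyNA(score)) {
    stop_validation("score filtering needs a score on every edge")
  }
  keep <- if (inclusive) score >= min_score else score > min_score
  g <- igraph::subgraph_from_edges(network, igraph::E(network)[keep],
                                   delete.vertices = TRUE)
  message(sprintf("score >= %.3f: kept %d/%d edges, %d nodes",
                  min_score, igraph::ecount(g), igraph::ecount(network),
                  igraph::vcount(g)))
  g
}

#' Raw degree per node
#'
#' @param network An `igraph`.
#' @return Named integer vector of unnormalised degrees.
#' @export
degree_centrality <- function(network) {
  d <- igraph::degree(network, normalized = FALSE)
  storage.mode(d) <- "integer"
  d
}

#' Shortest-path betweenness per node
#'
#' Betweenness on the undirected, unweighted graph (interaction scores are
#' ignored for path finding): for each node v, the sum over unordered node
#' pairs \{s, t\} of the fraction of shortest s-t paths passing through v.
#' Each unordered pair is counted once; no further normalisation.
#'
#' @param network An `igraph`.
#' @return Named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(network) {
  igraph::betweenness(network, directed = FALSE, weights = NA,
                      normalized = FALSE)
}

#' Hub filter: nodes above the mean degree
#'
#' Computes the mean of all node degrees and keeps nodes whose degree is
#' strictly greater ("larger than the average degree value"). Degrees are
#' computed once on the input graph; they are not recomputed after node
#' removal (single pass).
#'
#' @param network A non-empty `igraph`.
#' @return A list with `network` (the induced subgraph on the hubs) and
#'   `threshold` (the mean degree used).
#' @export
filter_hubs_by_mean_degree <- function(network) {
  if (igraph::vcount(network) == 0L) {
    stop_validation("cannot hub-filter an empty network")
  }
  deg <- igraph::degree(network)
  threshold <- mean(deg)
  hubs <- names(deg)[deg > threshold]
  g <- igraph::induced_subgraph(network, hubs)
  message(sprintf("mean degree %.3f: %d/%d nodes kept",
                  threshold, igraph::vcount(g), igraph::vcount(network)))
  list(network = g, threshold = threshold)
}

#' Export a network as a SIF-style edge table
#'
#' @param network An `igraph`.
#' @param path Output path.
#' @param relation Relation label for the middle column.
#' @return The path, invisibly.
#' @export
write_sif <- function(network, path, relation = "pp") {
  el <- igraph::as_edgelist(network)
  writeLines(sprintf("%s\t%s\t%s", el[, 1], relation, el[, 2]), path)
  invisible(path)
}
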