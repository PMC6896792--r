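# Bipartite network construction and topology analytics.
#
# Networks are undirected, simple igraph objects with vertex attributes:
#   name       node label (trimmed, case-sensitive)
#   partition  "a" (compounds, or pathways) / "b" (targets, or disease
#              systems)
#   type       logical igraph bipartite flag (TRUE = partition b)
#
# Metric conventions follow the Cytoscape NetworkAnalyzer definitions, since
# that is what network-pharmacology reports conventionally print: normalized
# betweenness with divisor (N-1)(N-2)/2; topological coefficient 0 for nodes
# with fewer than two neighbours; heterogeneity = coefficient of variation
# of the degree sequence (population variance); Freeman degree
# centralization.

#' Construct a bipartite network
#'
#' Low-level constructor. Labels are trimmed; the two partitions must be
#' disjoint (compounds/targets or pathways/diseases live in separate
#' namespaces, so a shared label is an error, not a merge). Duplicate edges
#' collapse to one with a message.
#'
#' @param a,b Character vectors of node labels for the two partitions
#'   (order of first appearance preserved; duplicates removed).
#' @param edges Two-column data frame (`from` in `a`, `to` in `b`), possibly
#'   empty.
#' @return An undirected igraph object with `partition` and `type` vertex
#'   attributes.
#' @export
bipartite_network <- function(a, b, edges = NULL) {
  a <- unique(norm_label(as.character(a)))
  b <- unique(norm_label(as.character(b)))
  if (any(!nzchar(a)) || any(!nzchar(b))) stop_input("empty node label")
  shared <- intersect(a, b)
  if (length(shared)) {
    stop_input("label(s) present in both partitions: ",
               paste(shared, collapse = ", "))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(a), name = a, partition = "a",
                            type = FALSE)
  g <- igraph::add_vertices(g, length(b), name = b, partition = "b",
                            type = TRUE)
  if (!is.null(edges) && nrow(edges)) {
    from <- norm_label(as.character(edges[[1L]]))
    to <- norm_label(as.character(edges[[2L]]))
    if (any(!from %in% a) || any(!to %in% b)) {
      stop_input("edge endpoint(s) outside the declared partitions")
    }
    key <- paste(from, to, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      message(sum(dup), " duplicate edge(s) collapsed")
      from <- from[!dup]
      to <- to[!dup]
    }
    g <- igraph::add_edges(g, rbind(from, to))
  }
  g
}

#' Build the compound-target network
#'
#' Builds the bipartite compound-target (C-T) graph from an association
#' table: one node per distinct compound and per distinct target, one edge
#' per distinct predicted interaction. With the packaged emulated
#' association table this reproduces the study's network composition of
#' 157 nodes (25 compounds + 132 targets) and 321 edges.
#'
#' @param assocs Association data frame (see [read_association_table()]).
#' @return Bipartite igraph: partition "a" = compounds, "b" = targets.
#' @export
build_compound_target_network <- function(assocs) {
  assocs <- validate_associations(assocs)
  bipartite_network(a = unique(assocs$compound),
                    b = unique(assocs$target),
                    edges = assocs[, c("compound", "target")])
}

#' Build the pathway-disease network
#'
#' Links enriched pathways to disease systems at organ level. Every pathway
#' in `records` becomes a node even if unlinked; links whose pathway ID does
#' not appear in `records` are skipped with a warning.
#'
#' @param records Enrichment data frame with a `pathway_id` column.
#' @param links Data frame with columns `pathway_id`, `disease_system`.
#' @return Bipartite igraph: partition "a" = pathways, "b" = disease
#'   systems.
#' @export
build_pathway_disease_network <- function(records, links) {
  if (!is.data.frame(records)) stop_input("'records' must be a data frame")
  require_columns(records, "pathway_id", "enrichment table")
  pathways <- unique(norm_label(as.character(records$pathway_id)))
  if (is.null(links) || !nrow(links)) {
    return(bipartite_network(a = pathways, b = character(0)))
  }
  require_columns(links, c("pathway_id", "disease_system"), "disease map")
  links$pathway_id <- norm_label(as.character(links$pathway_id))
  unknown <- !links$pathway_id %in% pathways
  if (any(unknown)) {
    warning(sum(unknown), " link(s) with unknown pathway ID skipped: ",
            paste(unique(links$pathway_id[unknown]), collapse = ", "))
    links <- links[!unknown, , drop = FALSE]
  }
  bipartite_network(a = pathways,
                    b = unique(norm_label(links$disease_system)),
                    edges = links[, c("pathway_id", "disease_system")])
}

#' Normalized betweenness centrality
#'
#' For each node, the sum over pairs of other nodes of the fraction of
#' shortest paths between them passing through the node, normalized by
#' `(N - 1)(N - 2) / 2` so values lie in `[0, 1]`. Pairs in different
#' components contribute zero; the normalization still uses the total node
#' count `N`. Graphs with fewer than three nodes return zeros.
#'
#' @param graph An igraph object.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  n <- igraph::vcount(graph)
  if (n == 0L) stop_input("graph has no nodes")
  if (n < 3L) {
    return(setNames(rep(0, n), igraph::V(graph)$name))
  }
  b <- igraph::betweenness(graph, directed = FALSE, normalized = TRUE)
  setNames(as.numeric(b), igraph::V(graph)$name)
}

#' Topological coefficient
#'
#' For a node n with degree `k >= 2`: the average, over all nodes m that
#' share at least one neighbour with n, of `J(n, m) / k`, where `J(n, m)` is
#' the number of neighbours shared by n and m, plus one if n and m are
#' directly linked. Nodes with fewer than two neighbours get 0 (in a C-T
#' network, a compound hitting a single target therefore scores 0,
#' flagging a non-synergistic, single-target mechanism).
#'
#' @param graph An igraph object.
#' @return Named numeric vector in `[0, 1]`.
#' @export
topological_coefficient <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  n <- igraph::vcount(graph)
  if (n == 0L) stop_input("graph has no nodes")
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  deg <- rowSums(A)
  S <- A %*% A  # S[i, j] = number of shared neighbours of i and j
  tc <- numeric(n)
  for (i in seq_len(n)) {
    if (deg[i] < 2) next
    partners <- which(S[i, ] > 0)
    partners <- partners[partners != i]
    if (!length(partners)) next
    J <- S[i, partners] + A[i, partners]
    tc[i] <- mean(J) / deg[i]
  }
  setNames(tc, igraph::V(graph)$name)
}

#' Network heterogeneity
#'
#' Coefficient of variation of the degree sequence: the square root of the
#' population variance of the degrees divided by the mean degree. Zero
#' exactly when all degrees are equal; larger values indicate hub bias.
#'
#' @param graph An igraph object with at least one node and mean degree > 0.
#' @return Nonnegative scalar.
#' @export
network_heterogeneity <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0L) stop_input("graph has no nodes")
  k <- igraph::degree(graph)
  mk <- mean(k)
  if (mk == 0) stop_input("heterogeneity undefined: mean degree is 0")
  sqrt(mean((k - mk)^2)) / mk
}

#' Network centralization
#'
#' Freeman degree centralization:
#' `(N / (N - 2)) * (k_max / (N - 1) - density)` with
#' `density = 2E / (N (N - 1))`. Equals 1 on a star and 0 on any regular
#' graph (in particular a complete graph). Undefined for fewer than three
#' nodes.
#'
#' @param graph A simple undirected igraph object with `N >= 3` nodes.
#' @return Scalar in `[0, 1]`.
#' @export
network_centralization <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  n <- igraph::vcount(graph)
  if (n < 3L) stop_input("centralization undefined for fewer than 3 nodes")
  k <- igraph::degree(graph)
  density <- 2 * igraph::ecount(graph) / (n * (n - 1))
  (n / (n - 2)) * (max(k) / (n - 1) - density)
}

#' Hub nodes
#'
#' Nodes whose degree exceeds `min_degree - 1` (the study's hub rule,
#' "degree higher than 10", is the default `min_degree = 11`), ranked by
#' degree descending, ties broken by betweenness descending then label
#' ascending.
#'
#' @param graph An igraph object.
#' @param partition `"all"` (default), `"a"` or `"b"`; restricts the
#'   candidates to one partition of a bipartite graph.
#' @param min_degree Minimum qualifying degree; default 11.
#' @return Data frame with columns `node`, `degree`, `betweenness`.
#' @export
hub_nodes <- function(graph, partition = c("all", "a", "b"),
                      min_degree = 11) {
  stopifnot(igraph::is_igraph(graph))
  partition <- match.arg(partition)
  min_degree <- check_count(min_degree, "min_degree")
  if (igraph::vcount(graph) == 0L) {
    return(data.frame(node = character(0), degree = integer(0),
                      betweenness = numeric(0), stringsAsFactors = FALSE))
  }
  deg <- igraph::degree(graph)
  btw <- betweenness_centrality(graph)
  nodes <- igraph::V(graph)$name
  keep <- deg >= min_degree
  if (partition != "all") {
    keep <- keep & igraph::V(graph)$partition == partition
  }
  out <- data.frame(node = nodes[keep], degree = as.integer(deg[keep]),
                    betweenness = as.numeric(btw[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, -out$betweenness, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full topology report
#'
#' Per-node degree, normalized betweenness and topological coefficient,
#' plus network-level node/edge counts, heterogeneity and centralization.
#'
#' @param graph An igraph object with at least 3 nodes and at least 1 edge.
#' @return A list of class `topology_report`: `nodes` (data frame sorted by
#'   degree descending, betweenness descending, label ascending), `n_nodes`,
#'   `n_edges`, `heterogeneity`, `centralization`.
#' @export
topology_report <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  deg <- igraph::degree(graph)
  nodes <- data.frame(node = igraph::V(graph)$name,
                      partition = igraph::V(graph)$partition,
                      degree = as.integer(deg),
                      betweenness = as.numeric(betweenness_centrality(graph)),
                      topological_coefficient =
                        as.numeric(topological_coefficient(graph)),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$degree, -nodes$betweenness, nodes$node), ,
                 drop = FALSE]
  rownames(nodes) <- NULL
  out <- list(nodes = nodes,
              n_nodes = as.integer(igraph::vcount(graph)),
              n_edges = as.integer(igraph::ecount(graph)),
              heterogeneity = network_heterogeneity(graph),
              centralization = network_centralization(graph))
  class(out) <- "topology_report"
  out
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Network topology:", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  cat(sprintf("  heterogeneity %.3f, centralization %.3f\n",
              x$heterogeneity, x$centralization))
  cat("Top nodes by degree:\n")
  print(head(x$nodes, 5L))
  invisible(x)
}
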