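# Network writers/readers: two-column edge list, Cytoscape SIF, GraphML.

#' Export a network
#'
#' Writes a bipartite network in one of three interchange formats:
#' \describe{
#'   \item{edgelist}{two-column tab-separated table with header
#'     `from`/`to`; `from` is partition "a". Round-trip safe via
#'     [read_edge_list()] for graphs without isolated nodes.}
#'   \item{sif}{Cytoscape simple interaction format, one
#'     `source\tinteracts\ttarget` line per edge.}
#'   \item{graphml}{GraphML XML with the `partition` vertex attribute,
#'     readable by Cytoscape and igraph.}
#' }
#'
#' @param graph A bipartite igraph (see [bipartite_network()]).
#' @param path Output file path.
#' @param format One of `"edgelist"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(graph, path, format = c("edgelist", "sif",
                                                   "graphml")) {
  stopifnot(igraph::is_igraph(graph))
  check_string(path, "path")
  format <- match.arg(format)
  el <- edge_table(graph)
  if (format == "edgelist") {
    write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    lines <- sprintf("%s\tinteracts\t%s", el$from, el$to)
    writeLines(lines, path)
  } else {
    igraph::write_graph(graph, path, format = "graphml")
  }
  invisible(path)
}

# edges oriented partition a -> partition b, sorted for byte-stable output
edge_table <- function(graph) {
  el <- igraph::as_edgelist(graph)
  if (!nrow(el)) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  part <- setNames(igraph::V(graph)$partition, igraph::V(graph)$name)
  flip <- part[el[, 1L]] == "b"
  out <- data.frame(from = ifelse(flip, el[, 2L], el[, 1L]),
                    to = ifelse(flip, el[, 1L], el[, 2L]),
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Read a two-column edge list
#'
#' Reconstructs a bipartite network from a tab-separated `from`/`to` edge
#' list as written by [export_network()]: partition "a" is the `from`
#' column, partition "b" the `to` column.
#'
#' @param path Path to the edge-list file.
#' @return A bipartite igraph object.
#' @export
read_edge_list <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) stop_input("edge list not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  require_columns(df, c("from", "to"), "edge list")
  bipartite_network(a = unique(df$from), b = unique(df$to), edges = df)
}

#' Write the per-node attribute table
#'
#' Writes the `nodes` table of a [topology_report()] (node, partition,
#' degree, betweenness, topological coefficient) as a tab-separated file.
#'
#' @param report A `topology_report` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_node_attributes <- function(report, path) {
  stopifnot(inherits(report, "topology_report"))
  check_string(path, "path")
  write.table(report$nodes, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
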