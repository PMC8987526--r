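#' Load a causal network from node and edge tables
#'
#' Reads the two-table tab-delimited network format: `nodes.tsv` with
#' columns `id`, `label`, `kind`, `measurable`, `genes` (semicolon-joined
#' symbols), `sufficient`, `expected_direction`; and `edges.tsv` with
#' columns `source`, `sign`, `target`, `mechanism`, `relationship_number`,
#' `feedback`. All graph invariants are validated on load.
#'
#' @param path directory containing `nodes.tsv` and `edges.tsv`, or the path
#'   to the nodes table itself (with `edges` then giving the edge table).
#' @param edges optional explicit path to the edge table.
#' @param outcome_id id of the terminal outcome node. By default the unique
#'   node with no outgoing edges.
#' @return a validated [causal_graph()].
#' @export
load_network <- function(path, edges = NULL, outcome_id = NULL) {
  if (is.null(edges)) {
    if (!dir.exists(path)) stop("network directory not found: ", path)
    nodes_path <- file.path(path, "nodes.tsv")
    edges_path <- file.path(path, "edges.tsv")
  } else {
    nodes_path <- path
    edges_path <- edges
  }
  for (p in c(nodes_path, edges_path)) {
    if (!file.exists(p)) stop("network file not found: ", p)
  }
  nodes <- utils::read.delim(nodes_path, stringsAsFactors = FALSE,
                             na.strings = "NA")
  edges <- utils::read.delim(edges_path, stringsAsFactors = FALSE,
                             na.strings = "NA")
  nodes$genes <- as.character(ifelse(is.na(nodes$genes), "", nodes$genes))
  if (is.null(outcome_id)) {
    sinks <- setdiff(nodes$id, edges$source)
    if (length(sinks) != 1) {
      stop("cannot infer outcome node; sink nodes: ",
           paste(sinks, collapse = ", "))
    }
    outcome_id <- sinks
  }
  causal_graph(nodes, edges, outcome_id)
}

#' Write a causal network to node and edge tables
#'
#' Round-trip writer for the format read by [load_network()].
#'
#' @param g a [causal_graph()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_network <- function(g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- g$nodes
  nodes$genes <- vapply(nodes$genes, paste, "", collapse = ";")
  paths <- file.path(dir, c("nodes.tsv", "edges.tsv"))
  utils::write.table(nodes, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(g$edges, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Export a causal network to GraphML
#'
#' GraphML keeps node labels, kinds, sufficiency flags and edge signs and is
#' readable by Cytoscape for visual overlay of expression states.
#'
#' @param g a [causal_graph()].
#' @param path output file.
#' @param node_states optional tibble from [node_states()]; if given, the
#'   `state` and `direction` columns are attached as node attributes.
#' @return invisibly, `path`.
#' @export
export_graphml <- function(g, path, node_states = NULL) {
  ig <- as_igraph(g, feedback = TRUE)
  idx <- match(igraph::V(ig)$name, g$nodes$id)
  igraph::V(ig)$label <- g$nodes$label[idx]
  igraph::V(ig)$kind <- g$nodes$kind[idx]
  igraph::V(ig)$measurable <- g$nodes$measurable[idx]
  igraph::V(ig)$sufficient <- g$nodes$sufficient[idx]
  igraph::V(ig)$genes <- vapply(g$nodes$genes[idx], paste, "", collapse = ";")
  if (!is.null(node_states)) {
    sidx <- match(igraph::V(ig)$name, node_states$node_id)
    igraph::V(ig)$state <- ifelse(is.na(sidx), "unobserved",
                                  node_states$state[sidx])
    igraph::V(ig)$direction <- ifelse(is.na(sidx), "none",
                                      node_states$direction[sidx])
  }
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Export a causal network as a SIF interaction list
#'
#' Simple interaction format: `source<TAB>sign<TAB>target`, one edge per
#' line. Lossy by design (mechanism, numbering and feedback flags are
#' dropped).
#'
#' @param g a [causal_graph()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
export_sif <- function(g, path) {
  writeLines(paste(g$edges$source, g$edges$sign, g$edges$target, sep = "\t"),
             path)
  invisible(path)
}

#' The bundled regenerative-proliferation Key-Event subnetwork
#'
#' Loads the curated causal subnetwork for the liver Key Event
#' "regenerative proliferation": 28 events (genes, proteins, complexes and
#' processes) in which repeated tissue injury engages Wnt and hypoxia
#' signaling, converging on dysregulated G1/S cell-cycle transition and
#' compensatory hepatocyte proliferation. Fifteen nodes are measurable
#' through a 25-gene expression panel ([rp_gene_panel()]); four
#' (Ccnd1, Rb1, Cdk4/6, Psmd10 -- five proteins, counting Cdk4 and Cdk6
#' separately) carry the curated sufficiency flag, meaning their
#' dysregulation in the expected direction licenses inferring the outcome.
#'
#' @return a validated [causal_graph()] with outcome `"proliferation"`.
#' @export
rp_network <- function() {
  load_network(system.file("extdata", "regenerative_proliferation",
                           package = "aopke", mustWork = TRUE),
               outcome_id = "proliferation")
}

#' The 25-gene measurable panel of the regenerative-proliferation network
#'
#' Gene symbols detected on the rat microarray platform that map onto the 15
#' measurable network nodes. Multi-gene nodes (e.g. the Wnt ligand family,
#' the destruction and Tcf/Lef complexes) pool several symbols; Cdk6
#' belongs to the Cdk4/6 node but is not part of the measured panel.
#'
#' @param g the network whose node gene lists define the panel; defaults to
#'   the bundled fixture.
#' @return tibble with columns `gene` and `node_id`.
#' @export
rp_gene_panel <- function(g = rp_network()) {
  nodes <- g$nodes[g$nodes$measurable, ]
  panel <- tibble::tibble(
    gene = unlist(nodes$genes),
    node_id = rep(nodes$id, vapply(nodes$genes, length, 1L)))
  panel[panel$gene != "Cdk6", ]
}
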