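#' @importFrom rlang .data
#' @importFrom stats median quantile rnorm runif sd setNames
#' @importFrom utils head
NULL

NODE_KINDS <- c("gene", "protein", "complex", "ligand_family", "process")
EDGE_SIGNS <- c("activates", "inhibits")
EDGE_MECHANISMS <- c("transcription", "protein_activity", "binding",
                     "degradation", "other")

#' Construct a validated causal Key-Event subnetwork
#'
#' A `causal_graph` is a signed, typed directed network of biological events
#' (genes, proteins, complexes, ligand families, processes) terminating in a
#' single outcome node. Edges carry a sign (`activates`/`inhibits`), a
#' mechanism, an optional literature relationship number, and a `feedback`
#' flag marking edges that close negative-feedback loops. Feedback edges are
#' excluded from conditional-independence reasoning (see [working_dag()]),
#' which requires an acyclic graph.
#'
#' Validation enforces: unique node ids; edge endpoints resolve; no
#' self-loops; measurable nodes carry at least one mapped gene symbol;
#' sufficient-flagged nodes are measurable with a declared expected
#' direction; the outcome node exists and has no outgoing edges; the
#' feedback-free subgraph is acyclic; and every non-outcome node reaches the
#' outcome by some directed path (feedback edges included, since a pure
#' feedback regulator such as a secreted pathway inhibitor may act only
#' through a feedback edge).
#'
#' @param nodes data frame with columns `id`, `label`, `kind`, `measurable`
#'   (logical), `genes` (list of character vectors, or `;`-joined strings),
#'   `sufficient` (logical), `expected_direction` (`up`/`down`/`none`).
#' @param edges data frame with columns `source`, `sign`, `target`,
#'   `mechanism`, `relationship_number` (integer or `NA`), `feedback`
#'   (logical).
#' @param outcome_id id of the terminal outcome node.
#' @return An object of class `causal_graph`: a list with tibbles `nodes`
#'   and `edges` and the `outcome_id`.
#' @seealso [load_network()], [rp_network()], [d_separated()],
#'   [sufficient_events()]
#' @export
causal_graph <- function(nodes, edges, outcome_id) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (!is.list(nodes$genes)) {
    nodes$genes <- lapply(nodes$genes, split_genes)
  }
  nodes$measurable <- as.logical(nodes$measurable)
  nodes$sufficient <- as.logical(nodes$sufficient)
  edges$feedback <- as.logical(edges$feedback)
  edges$relationship_number <- suppressWarnings(
    as.integer(edges$relationship_number))
  g <- structure(
    list(nodes = nodes, edges = edges, outcome_id = outcome_id),
    class = "causal_graph")
  validate_causal_graph(g)
  g
}

split_genes <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(trimws(x))) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

validate_causal_graph <- function(g) {
  nodes <- g$nodes
  edges <- g$edges
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  bad_kind <- setdiff(nodes$kind, NODE_KINDS)
  if (length(bad_kind)) stop("unknown node kind: ", paste(bad_kind, collapse = ", "))
  bad_dir <- setdiff(nodes$expected_direction, c("up", "down", "none"))
  if (length(bad_dir)) stop("unknown expected_direction: ", paste(bad_dir, collapse = ", "))
  missing_ref <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(missing_ref)) {
    stop("edge references missing node(s): ", paste(missing_ref, collapse = ", "))
  }
  if (any(edges$source == edges$target)) {
    stop("self-loop edge(s) on: ",
         paste(edges$source[edges$source == edges$target], collapse = ", "))
  }
  bad_sign <- setdiff(edges$sign, EDGE_SIGNS)
  if (length(bad_sign)) stop("unknown edge sign: ", paste(bad_sign, collapse = ", "))
  bad_mech <- setdiff(edges$mechanism, EDGE_MECHANISMS)
  if (length(bad_mech)) stop("unknown edge mechanism: ", paste(bad_mech, collapse = ", "))
  key <- paste(edges$source, edges$target, edges$sign)
  if (anyDuplicated(key[!is.na(edges$relationship_number)]) &&
      anyDuplicated(paste(key, edges$relationship_number))) {
    stop("duplicate relationship_number within a (source, target, sign)")
  }
  no_genes <- nodes$measurable & vapply(nodes$genes, length, 1L) == 0
  if (any(no_genes)) {
    stop("measurable node(s) without mapped genes: ",
         paste(nodes$id[no_genes], collapse = ", "))
  }
  bad_suff <- nodes$sufficient &
    (!nodes$measurable | nodes$expected_direction == "none")
  if (any(bad_suff)) {
    stop("sufficient node(s) must be measurable with an expected direction: ",
         paste(nodes$id[bad_suff], collapse = ", "))
  }
  if (!g$outcome_id %in% nodes$id) stop("missing outcome node: ", g$outcome_id)
  if (any(edges$source == g$outcome_id)) {
    stop("outcome node '", g$outcome_id, "' must have no outgoing edges")
  }
  ig_work <- as_igraph(g, feedback = FALSE)
  if (!igraph::is_dag(ig_work)) {
    cyc <- igraph::feedback_arc_set(ig_work)
    stop("cycle detected among non-feedback edges (e.g. involving edge ",
         paste(attr(cyc, "vnames"), collapse = ", "), ")")
  }
  ig_full <- as_igraph(g, feedback = TRUE)
  dist <- igraph::distances(ig_full, to = g$outcome_id, mode = "out")[, 1]
  unreachable <- setdiff(names(dist)[!is.finite(dist)], g$outcome_id)
  if (length(unreachable)) {
    stop("node(s) with no directed path to the outcome: ",
         paste(unreachable, collapse = ", "))
  }
  invisible(g)
}

#' @export
print.causal_graph <- function(x, ...) {
  cat("<causal_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", sum(x$edges$feedback), " feedback); outcome: ",
      x$outcome_id, "\n", sep = "")
  cat("  measurable nodes: ", sum(x$nodes$measurable),
      "; mapped genes: ", length(unlist(x$nodes$genes)), "\n", sep = "")
  invisible(x)
}

#' Convert a causal graph to an igraph object
#'
#' @param g a [causal_graph()].
#' @param feedback include feedback-flagged edges? The default `TRUE` gives
#'   the full network; `FALSE` gives the acyclic working graph used for
#'   independence queries.
#' @return an `igraph` directed graph whose vertex names are node ids and
#'   whose edges carry `sign`, `mechanism` and `feedback` attributes.
#' @export
as_igraph <- function(g, feedback = TRUE) {
  ed <- g$edges
  if (!feedback) ed <- ed[!ed$feedback, , drop = FALSE]
  igraph::graph_from_data_frame(
    ed[, c("source", "target", "sign", "mechanism", "feedback")],
    directed = TRUE,
    vertices = data.frame(name = g$nodes$id, stringsAsFactors = FALSE))
}

#' Feedback-free working DAG of a causal network
#'
#' Removes the edges flagged as feedback (the negative-feedback loops, e.g.
#' transcriptional induction of Axin2 and Dkk1 by Tcf/Lef) so that the
#' remaining forward cascade is an acyclic graph on which d-separation is
#' defined. Node set is unchanged.
#'
#' @param g a [causal_graph()].
#' @return a `causal_graph` containing only non-feedback edges; guaranteed
#'   acyclic (an error identifying a cycle is raised otherwise).
#' @export
working_dag <- function(g) {
  edges <- g$edges[!g$edges$feedback, , drop = FALSE]
  out <- structure(
    list(nodes = g$nodes, edges = edges, outcome_id = g$outcome_id),
    class = "causal_graph")
  ig <- as_igraph(out)
  if (!igraph::is_dag(ig)) {
    stop("graph is still cyclic after removing feedback edges")
  }
  out
}

#' Parents of a node in the working DAG
#'
#' Sources of direct causal edges into `v`, with feedback edges excluded:
#' the events whose state the node directly depends on under the local
#' Markov property.
#'
#' @param g a [causal_graph()].
#' @param v a node id.
#' @return character vector of parent node ids (possibly empty).
#' @export
node_parents <- function(g, v) {
  if (!v %in% g$nodes$id) stop("unknown node id: ", v)
  ed <- g$edges
  sort(unique(ed$source[!ed$feedback & ed$target == v]))
}

node_descendants <- function(g, v) {
  ig <- as_igraph(g, feedback = FALSE)
  ids <- names(igraph::subcomponent(ig, v, mode = "out"))
  setdiff(ids, v)
}
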