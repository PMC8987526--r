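#' Test d-separation of two events in the causal network
#'
#' Decides whether `a` and `b` are conditionally independent given the set
#' `given` under the standard d-separation criterion on the feedback-free
#' working DAG: a path is blocked at a chain or fork node that is observed,
#' and at a collider unless the collider or one of its descendants is
#' observed. Edge signs are ignored (separation is sign-blind).
#'
#' The implementation uses the moralized-ancestral-graph criterion: restrict
#' to the ancestors of `a`, `b` and the conditioning set, marry co-parents,
#' drop edge directions, delete the conditioning nodes, and test whether `a`
#' and `b` are disconnected. This is equivalent to checking every path
#' against the blocking rules, and is verified against a brute-force
#' path-enumeration oracle in the test suite.
#'
#' @param g a [causal_graph()].
#' @param a,b node ids; must differ and not lie in `given`.
#' @param given character vector of observed node ids (may be empty).
#' @return `TRUE` if `a` and `b` are d-separated given `given`.
#' @export
d_separated <- function(g, a, b, given = character()) {
  ids <- g$nodes$id
  unknown <- setdiff(c(a, b, given), ids)
  if (length(unknown)) stop("unknown node id: ", paste(unknown, collapse = ", "))
  if (a == b) stop("query nodes must differ")
  if (a %in% given || b %in% given) {
    stop("query nodes must not be in the conditioning set")
  }
  ig <- as_igraph(g, feedback = FALSE)
  anc <- unique(c(
    unlist(lapply(c(a, b, given), function(v)
      names(igraph::subcomponent(ig, v, mode = "in"))))))
  sub <- igraph::induced_subgraph(ig, anc)
  # moralize: connect all co-parent pairs, then drop directions
  el <- igraph::as_edgelist(sub)
  vnames <- igraph::V(sub)$name
  marry <- list()
  for (v in vnames) {
    pa <- el[el[, 2] == v, 1]
    if (length(pa) > 1) {
      marry[[v]] <- t(utils::combn(pa, 2))
    }
  }
  moral_el <- rbind(el, do.call(rbind, marry))
  moral <- igraph::graph_from_edgelist(moral_el, directed = FALSE)
  moral <- igraph::add_vertices(
    moral, length(setdiff(vnames, igraph::V(moral)$name)),
    name = setdiff(vnames, igraph::V(moral)$name))
  keep <- setdiff(igraph::V(moral)$name, given)
  moral <- igraph::induced_subgraph(moral, keep)
  if (!(a %in% igraph::V(moral)$name) || !(b %in% igraph::V(moral)$name)) {
    return(TRUE)
  }
  comp <- igraph::components(moral)$membership
  unname(comp[a] != comp[b])
}

#' Local Markov conditional independence of a node from a non-descendant
#'
#' Under the local Markov property, the state of an event depends only on
#' its direct causal parents: a node is conditionally independent of any
#' non-descendant given its parents. This helper phrases that as a
#' d-separation query `v` vs `u` given `parents(v)` on the working DAG
#' (if `u` is itself a parent it is removed from the conditioning set, so
#' the query tests direct dependence).
#'
#' @param g a [causal_graph()].
#' @param v a node id.
#' @param u a node id that is not a descendant of `v` in the working DAG.
#' @return `TRUE` if `v` and `u` are d-separated given the parents of `v`.
#' @export
locally_markov_independent <- function(g, v, u) {
  if (!v %in% g$nodes$id) stop("unknown node id: ", v)
  if (!u %in% g$nodes$id) stop("unknown node id: ", u)
  if (u %in% node_descendants(g, v)) {
    stop("'", u, "' is not a non-descendant of '", v, "'")
  }
  d_separated(g, v, u, setdiff(node_parents(g, v), u))
}

#' Identify events sufficient to infer the network outcome
#'
#' A sufficient event (in the sufficient-component-cause sense: a cause
#' whose occurrence inevitably produces the effect) is taken to be a
#' measurable node that (i) sits immediately upstream of the outcome --
#' within `max_depth` causal steps of the process layer that directly
#' drives the outcome, i.e. a directed path to the outcome of length at
#' most `max_depth + 1` in the working DAG -- and (ii) carries the curated
#' sufficiency flag backed by intervention evidence. Because the curated
#' literature criterion is partly informal, the function returns the
#' conjunction together with an audit of the disagreements between the two
#' criteria rather than silently preferring one.
#'
#' @param g a [causal_graph()].
#' @param max_depth maximum number of causal steps between a candidate and
#'   the outcome's immediate driver (default 2). `max_depth = 0` keeps only
#'   measurable direct drivers of the outcome.
#' @return an object of class `sufficiency_audit`: list with
#'   \describe{
#'     \item{sufficient}{node ids satisfying both criteria;}
#'     \item{proximal}{measurable ids satisfying the proximity criterion;}
#'     \item{flagged}{measurable ids carrying the curated flag;}
#'     \item{proximal_not_flagged, flagged_not_proximal}{the audit;}
#'     \item{proteins}{gene symbols mapped to the sufficient nodes
#'       (complex members counted separately);}
#'     \item{max_depth}{the depth used.}
#'   }
#' @export
sufficient_events <- function(g, max_depth = 2) {
  stopifnot(is.numeric(max_depth), max_depth >= 0)
  wd <- working_dag(g)
  ig <- as_igraph(wd)
  dist <- igraph::distances(ig, to = g$outcome_id, mode = "out")[, 1]
  meas <- g$nodes$id[g$nodes$measurable]
  proximal <- intersect(meas, names(dist)[dist <= max_depth + 1])
  flagged <- intersect(meas, g$nodes$id[g$nodes$sufficient])
  suff <- intersect(proximal, flagged)
  structure(list(
    sufficient = sort(suff),
    proximal = sort(proximal),
    flagged = sort(flagged),
    proximal_not_flagged = sort(setdiff(proximal, flagged)),
    flagged_not_proximal = sort(setdiff(flagged, proximal)),
    proteins = sort(unlist(g$nodes$genes[g$nodes$id %in% suff])),
    max_depth = max_depth
  ), class = "sufficiency_audit")
}

#' @export
print.sufficiency_audit <- function(x, ...) {
  cat("<sufficiency_audit> depth ", x$max_depth, "\n", sep = "")
  cat("  sufficient events: ", paste(x$sufficient, collapse = ", "), "\n",
      sep = "")
  cat("  proteins: ", paste(x$proteins, collapse = ", "), "\n", sep = "")
  if (length(x$proximal_not_flagged)) {
    cat("  proximal but not curated-sufficient: ",
        paste(x$proximal_not_flagged, collapse = ", "), "\n", sep = "")
  }
  if (length(x$flagged_not_proximal)) {
    cat("  curated-sufficient but not proximal: ",
        paste(x$flagged_not_proximal, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
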