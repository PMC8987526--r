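#' Map gene-level calls onto network node states
#'
#' Uses transcript-level differential expression as a surrogate for node
#' activity: a measurable node is `active` when at least one of its mapped
#' genes is called `up` or `down`, `inactive` when all mapped genes were
#' tested and called `nochange`, and `unobserved` when none of its genes
#' appear in the calls. The realized direction is `up`/`down` when all
#' non-`nochange` genes agree and `mixed` otherwise; `mixed` nodes never
#' trigger sufficiency. Nodes whose biological activity is
#' post-transcriptional (proteins and complexes) carry a
#' `surrogate_caveat` flag, since transcript changes need not track
#' protein activity in time or abundance.
#'
#' @param g a [causal_graph()].
#' @param gene_calls tibble of [gene_level_calls()] for a single exposure
#'   group: columns `gene`, `call`.
#' @return tibble with `node_id`, `state`, `direction`, `genes_observed`,
#'   `genes_up`, `genes_down`, `surrogate_caveat`; gene symbols not mapped
#'   to any node in attribute `"unmapped_genes"`.
#' @export
node_states <- function(g, gene_calls) {
  calls <- tibble::as_tibble(gene_calls)
  if (length(unique(calls[["group_id"]] %||% "g")) > 1) {
    stop("node_states expects calls for a single exposure group")
  }
  nodes <- g$nodes[g$nodes$measurable, ]
  all_genes <- unlist(nodes$genes)
  unmapped <- setdiff(calls$gene, all_genes)
  rows <- lapply(seq_len(nrow(nodes)), function(i) {
    genes <- nodes$genes[[i]]
    obs <- calls[calls$gene %in% genes, ]
    up <- obs$gene[obs$call == "up"]
    down <- obs$gene[obs$call == "down"]
    state <- if (nrow(obs) == 0) "unobserved"
             else if (length(up) + length(down) > 0) "active"
             else "inactive"
    direction <- if (length(up) > 0 && length(down) > 0) "mixed"
                 else if (length(up) > 0) "up"
                 else if (length(down) > 0) "down"
                 else "none"
    tibble::tibble(
      node_id = nodes$id[i], state = state, direction = direction,
      genes_observed = paste(obs$gene, collapse = ";"),
      genes_up = paste(up, collapse = ";"),
      genes_down = paste(down, collapse = ";"),
      surrogate_caveat = nodes$kind[i] %in% c("protein", "complex"))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "unmapped_genes") <- unmapped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Infer Key-Event activation from node states
#'
#' The Key Event is inferred active when at least one sufficient event
#' (see [sufficient_events()]) is active in its expected direction --
#' Ccnd1, Cdk4/6 or Psmd10 up, or Rb1 down, in the bundled network. A
#' sufficient node observed in the opposite direction is recorded but
#' neither triggers nor argues against activation; activity of any number
#' of non-sufficient nodes alone never licenses the inference, because the
#' outcome is conditionally independent of them given the events between
#' them and the outcome.
#'
#' @param g a [causal_graph()].
#' @param states tibble from [node_states()].
#' @param group optional named list or one-row tibble of group metadata
#'   (`chemical`, `dose_level`, `time_value`, `time_unit`) copied into the
#'   report.
#' @return an object of class `ke_report`: list with `ke_active`,
#'   `triggering_nodes`, `sufficient_wrong_direction`,
#'   `active_nonsufficient`, `flags` (narrative notes), `states`, and
#'   `group`.
#' @export
infer_ke <- function(g, states, group = NULL) {
  suff <- sufficient_events(g)$sufficient
  st <- tibble::as_tibble(states)
  expected <- setNames(g$nodes$expected_direction, g$nodes$id)
  active <- st$node_id[st$state == "active"]
  triggering <- intersect(
    active[st$direction[match(active, st$node_id)] ==
             expected[active]], suff)
  wrong_dir <- setdiff(intersect(active, suff), triggering)
  nonsuff <- setdiff(active, suff)
  flags <- character(0)
  if (length(nonsuff) && !length(triggering)) {
    flags <- c(flags, "non-sufficient node active only")
  }
  if (length(wrong_dir)) {
    flags <- c(flags, paste0("sufficient node in unexpected direction: ",
                             paste(wrong_dir, collapse = ", ")))
  }
  caveat <- st$node_id[st$node_id %in% c(triggering, nonsuff, wrong_dir) &
                         st$surrogate_caveat]
  if (length(caveat)) {
    flags <- c(flags, paste0("transcript used as surrogate for protein ",
                             "activity: ", paste(caveat, collapse = ", ")))
  }
  structure(list(
    ke_active = length(triggering) > 0,
    triggering_nodes = sort(triggering),
    sufficient_wrong_direction = sort(wrong_dir),
    active_nonsufficient = sort(nonsuff),
    flags = flags,
    states = st,
    group = group
  ), class = "ke_report")
}

#' @export
print.ke_report <- function(x, ...) {
  hdr <- if (!is.null(x$group)) {
    paste0(" [", paste(unlist(x$group), collapse = " "), "]")
  } else ""
  cat("<ke_report>", hdr, " KE ",
      if (x$ke_active) "ACTIVE" else "inactive", "\n", sep = "")
  if (length(x$triggering_nodes)) {
    cat("  triggering sufficient nodes: ",
        paste(x$triggering_nodes, collapse = ", "), "\n", sep = "")
  }
  if (length(x$active_nonsufficient)) {
    cat("  active non-sufficient nodes (context): ",
        paste(x$active_nonsufficient, collapse = ", "), "\n", sep = "")
  }
  for (f in x$flags) cat("  note: ", f, "\n", sep = "")
  invisible(x)
}

#' Per-group Key-Event verdicts for one chemical
#'
#' Applies [node_states()] and [infer_ke()] to every exposure group of one
#' chemical, ordered by sacrifice time then dose, and summarizes the first
#' group in which the Key Event is inferred active.
#'
#' @param g a [causal_graph()].
#' @param gene_calls tibble of [gene_level_calls()] covering all treatment
#'   groups of one chemical (columns `gene`, `group_id`, `call`, and the
#'   group metadata columns `chemical`, `dose_level`, `time_value`,
#'   `time_unit`).
#' @return an object of class `chemical_report`: list with `chemical`,
#'   `verdicts` (tibble: one row per group with `ke_active`,
#'   `triggering_nodes`, `active_nonsufficient`, `flags`),
#'   `first_active` (group id or `NA`), and `reports` (the per-group
#'   [infer_ke()] objects).
#' @export
chemical_report <- function(g, gene_calls) {
  calls <- tibble::as_tibble(gene_calls)
  if (nrow(calls) == 0) {
    return(structure(list(chemical = NA_character_,
                          verdicts = tibble::tibble(),
                          first_active = NA_character_,
                          reports = list()),
                     class = "chemical_report"))
  }
  chem <- unique(calls[["chemical"]] %||% NA_character_)
  if (length(chem) > 1) stop("chemical_report expects a single chemical")
  meta <- dplyr::distinct(calls, .data$group_id, .data$dose_level,
                          .data$time_value, .data$time_unit)
  meta <- dplyr::arrange(meta, .data$time_value,
                         factor(.data$dose_level,
                                levels = c("low", "mid", "high")))
  reports <- lapply(seq_len(nrow(meta)), function(i) {
    gc <- calls[calls$group_id == meta$group_id[i], ]
    infer_ke(g, node_states(g, gc),
             group = c(list(chemical = chem), as.list(meta[i, ])))
  })
  names(reports) <- meta$group_id
  verdicts <- dplyr::bind_cols(
    tibble::tibble(chemical = chem), meta,
    tibble::tibble(
      ke_active = vapply(reports, function(r) r$ke_active, TRUE,
                         USE.NAMES = FALSE),
      triggering_nodes = vapply(reports, function(r)
        paste(r$triggering_nodes, collapse = ";"), "", USE.NAMES = FALSE),
      active_nonsufficient = vapply(reports, function(r)
        paste(r$active_nonsufficient, collapse = ";"), "",
        USE.NAMES = FALSE),
      flags = vapply(reports, function(r)
        paste(r$flags, collapse = " | "), "", USE.NAMES = FALSE)))
  first_active <- if (any(verdicts$ke_active)) {
    verdicts$group_id[which(verdicts$ke_active)[1]]
  } else NA_character_
  structure(list(chemical = chem, verdicts = verdicts,
                 first_active = first_active, reports = reports),
            class = "chemical_report")
}

#' @export
print.chemical_report <- function(x, ...) {
  cat("<chemical_report> ", x$chemical, ": KE active in ",
      sum(x$verdicts$ke_active), "/", nrow(x$verdicts), " groups",
      if (!is.na(x$first_active)) paste0(" (first: ", x$first_active, ")"),
      "\n", sep = "")
  invisible(x)
}
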