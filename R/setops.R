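# Set-algebraic combination of multiple design graphs under the load
# predicates (union, difference, intersection) and the two node-level modes.

.edge_id <- function(e) {
  paste(e$subject, e$predicate, ifelse(is.na(e$role), "", e$role), e$object,
        sep = "\r")
}

#' Combine a collection of design graphs under a load predicate
#'
#' Element identity is the node key for nodes and the
#' (subject, predicate, role, object) tuple for edges.
#' \describe{
#'   \item{union}{all elements in all graphs.}
#'   \item{intersection}{elements present in every graph.}
#'   \item{difference}{elements present in exactly one graph.}
#' }
#' The result is repaired to referential closure: an edge survives only if
#' both of its endpoint nodes survive; nodes are elements in their own right
#' and are never dropped because an incident edge was. When node property
#' maps conflict between graphs in a union, the first-loaded graph's value
#' wins and the conflict is logged.
#'
#' @param graphs Named (labels must be unique) or unnamed list of
#'   `design_graph` objects, in load order.
#' @param predicate One of `union`, `difference`, `intersection`.
#' @return A `design_graph`.
#' @export
combine <- function(graphs, predicate = c("union", "difference",
                                          "intersection")) {
  predicate <- match.arg(predicate)
  if (!length(graphs)) stop("empty graph collection")
  stopifnot(all(vapply(graphs, inherits, TRUE, "design_graph")))
  if (!is.null(names(graphs)) && anyDuplicated(names(graphs))) {
    stop("graph labels must be unique")
  }
  k <- length(graphs)
  node_tab <- table(unlist(lapply(graphs, function(g)
    unique(names(g$nodes)))))
  edge_tab <- table(unlist(lapply(graphs, function(g)
    unique(.edge_id(g$edges)))))
  keep_count <- switch(predicate,
                       union = 1L,
                       intersection = k,
                       difference = NA_integer_)
  sel <- function(tab) {
    if (predicate == "difference") names(tab)[tab == 1L]
    else names(tab)[tab >= keep_count]
  }
  keep_nodes <- sel(node_tab)
  keep_edges <- sel(edge_tab)

  out <- design_graph()
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    for (key in names(g$nodes)) {
      if (!key %in% keep_nodes) next
      n <- g$nodes[[key]]
      if (is.null(out$nodes[[key]])) {
        out$nodes[[key]] <- n
      } else {
        prev <- out$nodes[[key]]
        clash <- intersect(names(prev$properties), names(n$properties))
        clash <- clash[prev$properties[clash] != n$properties[clash]]
        if (length(clash)) {
          cg_log("warn", "setops", sprintf(
            "node %s: conflicting properties (%s); first-loaded value kept",
            key, paste(clash, collapse = ", ")))
        }
        add <- setdiff(names(n$properties), names(prev$properties))
        prev$properties <- c(prev$properties, n$properties[add])
        out$nodes[[key]] <- prev
      }
    }
  }
  for (g in graphs) {
    e <- g$edges
    ids <- .edge_id(e)
    for (i in seq_len(nrow(e))) {
      if (!ids[i] %in% keep_edges) next
      if (!e$subject[i] %in% keep_nodes || !e$object[i] %in% keep_nodes) next
      out <- graph_add_edge(out, e$subject[i], e$predicate[i], e$object[i],
                            role = e$role[i], weight = e$weight[i])
    }
  }
  roots <- unique(unlist(lapply(graphs, `[[`, "roots")))
  roots <- roots[roots %in% names(out$nodes)]
  roots <- roots[vapply(roots, function(r)
    out$nodes[[r]]$type == "Engineered-Region", TRUE)]
  out$roots <- sort(roots)
  out
}

#' Node-level difference and intersection of two design graphs
#'
#' `node_difference` keeps the nodes present in exactly one of the two
#' graphs, with the edges induced among the survivors; `node_intersection`
#' keeps the nodes present in both, with edges induced from the union of
#' the two edge sets restricted to surviving nodes.
#'
#' @param a,b `design_graph` objects.
#' @param mode `node_difference` or `node_intersection`.
#' @return A `design_graph`.
#' @export
node_mode <- function(a, b, mode = c("node_difference", "node_intersection")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "design_graph"), inherits(b, "design_graph"))
  ka <- names(a$nodes); kb <- names(b$nodes)
  keep <- if (mode == "node_difference") {
    union(setdiff(ka, kb), setdiff(kb, ka))
  } else {
    intersect(ka, kb)
  }
  out <- design_graph()
  for (key in keep) {
    n <- if (!is.null(a$nodes[[key]])) a$nodes[[key]] else b$nodes[[key]]
    out$nodes[[key]] <- n
  }
  all_edges <- rbind(a$edges, b$edges)
  for (i in seq_len(nrow(all_edges))) {
    e <- all_edges[i, ]
    if (e$subject %in% keep && e$object %in% keep) {
      out <- graph_add_edge(out, e$subject, e$predicate, e$object,
                            role = e$role, weight = e$weight)
    }
  }
  roots <- union(a$roots, b$roots)
  roots <- roots[roots %in% keep]
  roots <- roots[vapply(roots, function(r)
    out$nodes[[r]]$type == "Engineered-Region", TRUE)]
  out$roots <- sort(roots)
  out
}
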