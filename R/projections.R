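# Analytical views of the canonical graph: full, parts hierarchy,
# interaction-verbose, collapsed interaction, derived protein network;
# plus per-projection network statistics and shortest-path provenance.

.node_prop <- function(g, key, name, default = NA_character_) {
  n <- g$nodes[[key]]
  if (is.null(n)) return(default)
  v <- unname(n$properties[name])
  if (length(v) != 1 || is.na(v)) default else v
}

.node_type <- function(g, key) {
  n <- g$nodes[[key]]
  if (is.null(n)) NA_character_ else n$type
}

.interaction_type_of <- function(g, key) {
  it <- g$edges[g$edges$predicate == "interactionType" &
                  g$edges$subject == key, , drop = FALSE]
  if (!nrow(it)) return(NA_character_)
  term <- it$object[1]
  hit <- names(.sbo_interaction_terms)[.sbo_interaction_terms == term]
  if (length(hit)) hit[1] else NA_character_
}

.empty_proj_edges <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), role = character(), weight = numeric(),
             provenance = character(), path_length = integer(),
             stringsAsFactors = FALSE)
}

.proj_sort <- function(p) {
  p$nodes <- sort(p$nodes)
  e <- p$edges
  if (nrow(e)) {
    ord <- order(e$subject, e$predicate, e$object,
                 ifelse(is.na(e$role), "", e$role))
    e <- e[ord, , drop = FALSE]
    rownames(e) <- NULL
    p$edges <- e
  }
  p
}

# Deterministic breadth-first shortest path on the undirected skeleton of
# the canonical graph; ties between equal-length paths are broken by the
# lexicographically smallest key sequence (predecessor chosen as the
# smallest key among shortest predecessors).
.bfs_shortest_path <- function(g, from, to) {
  if (from == to) return(from)
  adj <- .undirected_adjacency(g)
  dist <- stats::setNames(rep(NA_integer_, length(adj)), names(adj))
  pred <- stats::setNames(rep(NA_character_, length(adj)), names(adj))
  if (!from %in% names(adj) || !to %in% names(adj)) return(NULL)
  dist[from] <- 0L
  frontier <- from
  while (length(frontier) && is.na(dist[to])) {
    frontier <- sort(frontier)
    nxt <- character()
    for (u in frontier) {
      for (w in adj[[u]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[u] + 1L
          pred[w] <- u
          nxt <- c(nxt, w)
        } else if (dist[w] == dist[u] + 1L && u < pred[w]) {
          pred[w] <- u
        }
      }
    }
    frontier <- unique(nxt)
  }
  if (is.na(dist[to])) return(NULL)
  path <- to
  while (path[1] != from) path <- c(pred[path[1]], path)
  path
}

.undirected_adjacency <- function(g) {
  adj <- stats::setNames(vector("list", length(g$nodes)), names(g$nodes))
  e <- g$edges
  for (i in seq_len(nrow(e))) {
    s <- e$subject[i]; o <- e$object[i]
    adj[[s]] <- union(adj[[s]], o)
    adj[[o]] <- union(adj[[o]], s)
  }
  adj
}

.participants <- function(g, ikey) {
  pp <- g$edges[g$edges$predicate == "hasParticipant" &
                  g$edges$subject == ikey, , drop = FALSE]
  pp[order(pp$object), , drop = FALSE]
}

# Collapse one interaction node into directed edges active -> passive.
# Returns a proj-edge data frame; interactions with no resolvable role
# qualifier contribute nothing (a warning is logged).
.collapse_interaction <- function(g, ikey) {
  itype <- .interaction_type_of(g, ikey)
  pp <- .participants(g, ikey)
  out <- .empty_proj_edges()
  if (is.na(itype)) {
    cg_log("warn", "projections",
           sprintf("interaction %s has no recognised interaction type; skipped",
                   ikey))
    return(out)
  }
  act <- pp$object[pp$role %in% .active_roles & !is.na(pp$role)]
  pas <- pp$object[pp$role %in% .passive_roles & !is.na(pp$role)]
  if (any(is.na(pp$role)) || !length(act) || !length(pas)) {
    cg_log("warn", "projections",
           sprintf("interaction %s has participants with missing role qualifiers; edge skipped",
                   ikey))
  }
  pred <- unname(.interaction_predicate_map[itype])
  for (a in act) {
    for (p in pas) {
      path <- .bfs_shortest_path(g, a, p)
      if (is.null(path)) path <- c(a, ikey, p)
      out <- rbind(out, data.frame(
        subject = a, predicate = pred, object = p, role = NA_character_,
        weight = NA_real_, provenance = paste(path, collapse = "|"),
        path_length = length(path) - 1L, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Project a design graph into an analytical view
#'
#' Views are derived graphs focusing on one aspect of the design:
#' \describe{
#'   \item{full}{every node and edge verbatim, each edge with path length 1.}
#'   \item{hierarchy}{genetic part nodes and `hasPart` containment edges
#'     only.}
#'   \item{interaction_verbose}{molecular entities plus explicit
#'     `Interaction` nodes with their role-qualified participation edges.}
#'   \item{interaction}{each interaction node collapsed to directed edges
#'     from every active participant (inhibitor, stimulator, template) to
#'     every passive participant (inhibited, stimulated, product), the
#'     predicate mapped from the interaction type (repression to
#'     `represses`, stimulation to `activates`, genetic production to
#'     `produces`); provenance runs through the interaction node.}
#'   \item{protein_network}{the interaction view with `produces` edges
#'     contracted: coding sequences are replaced by the proteins they
#'     produce, only proteins, complexes and small molecules remain, and a
#'     regulatory edge onto a promoter or CDS is re-targeted to the
#'     protein(s) produced downstream of that target within the same root
#'     design.}
#' }
#' Every projected edge records its provenance: the shortest path in the
#' canonical graph (undirected, lexicographic tie-break) connecting the two
#' linked nodes, and that path's length.
#'
#' @param g A `design_graph`.
#' @param view_name One of `full`, `hierarchy`, `interaction_verbose`,
#'   `interaction`, `protein_network`.
#' @return A `projection_graph`: list with `view`, sorted `nodes` (keys),
#'   `node_types`, `edges` (with `provenance` and `path_length`), `source`.
#' @export
project <- function(g, view_name) {
  stopifnot(inherits(g, "design_graph"))
  if (!view_name %in% .registered_views) {
    stop(sprintf("unregistered view '%s'", view_name))
  }
  keys <- names(g$nodes)
  types <- vapply(g$nodes, `[[`, "", "type")
  edges <- .empty_proj_edges()
  nodes <- character()

  if (view_name == "full") {
    nodes <- keys
    e <- g$edges
    if (nrow(e)) {
      edges <- data.frame(subject = e$subject, predicate = e$predicate,
                          object = e$object, role = e$role, weight = e$weight,
                          provenance = paste(e$subject, e$object, sep = "|"),
                          path_length = 1L, stringsAsFactors = FALSE)
    }
  } else if (view_name == "hierarchy") {
    nodes <- keys[types[keys] %in% .genetic_part_types]
    hp <- g$edges[g$edges$predicate == "hasPart" &
                    g$edges$subject %in% nodes &
                    g$edges$object %in% nodes, , drop = FALSE]
    if (nrow(hp)) {
      edges <- data.frame(subject = hp$subject, predicate = "hasPart",
                          object = hp$object, role = NA_character_,
                          weight = NA_real_,
                          provenance = paste(hp$subject, hp$object, sep = "|"),
                          path_length = 1L, stringsAsFactors = FALSE)
    }
  } else if (view_name == "interaction_verbose") {
    nodes <- keys[types[keys] %in% c(.entity_types, "Interaction")]
    pp <- g$edges[g$edges$predicate == "hasParticipant" &
                    g$edges$subject %in% nodes &
                    g$edges$object %in% nodes, , drop = FALSE]
    if (nrow(pp)) {
      edges <- data.frame(subject = pp$subject, predicate = "hasParticipant",
                          object = pp$object, role = pp$role,
                          weight = NA_real_,
                          provenance = paste(pp$subject, pp$object, sep = "|"),
                          path_length = 1L, stringsAsFactors = FALSE)
    }
  } else if (view_name %in% c("interaction", "protein_network")) {
    nodes <- keys[types[keys] %in% .entity_types]
    ikeys <- sort(keys[types[keys] == "Interaction"])
    for (ik in ikeys) edges <- rbind(edges, .collapse_interaction(g, ik))
    # collapsed regulatory edges stored directly in the canonical graph
    # (e.g. interaction lists attached during repository merging)
    direct <- g$edges[g$edges$predicate %in%
                        unname(.interaction_predicate_map), , drop = FALSE]
    if (nrow(direct)) {
      edges <- rbind(edges, data.frame(
        subject = direct$subject, predicate = direct$predicate,
        object = direct$object, role = NA_character_, weight = NA_real_,
        provenance = paste(direct$subject, direct$object, sep = "|"),
        path_length = 1L, stringsAsFactors = FALSE))
    }
    if (view_name == "protein_network") {
      res <- .contract_protein_network(g, nodes, edges)
      nodes <- res$nodes
      edges <- res$edges
    }
  }

  p <- structure(list(view = view_name, nodes = unname(nodes),
                      node_types = types[nodes],
                      edges = edges, source = g),
                 class = "projection_graph")
  .proj_sort(p)
}

# protein-network contraction: map every CDS to the protein(s) it produces,
# re-target regulatory edges on promoters/CDS to the proteins produced
# downstream within the same root design, keep entity nodes only.
.contract_protein_network <- function(g, nodes, edges) {
  types <- vapply(g$nodes, `[[`, "", "type")
  produces <- edges[edges$predicate == "produces", , drop = FALSE]
  cds_to_protein <- split(produces$object, produces$subject)
  root_of <- .root_assignment(g)
  parent_of <- .haspart_parents(g)

  # proteins downstream of a regulatory target (promoter or CDS): the CDS
  # itself, or sibling CDS under the same containing unit, mapped through
  # production, confined to the same root design
  target_proteins <- function(tkey) {
    ttype <- types[tkey]
    if (!is.na(ttype) && ttype %in% c("Protein", "Complex", "SmallMolecule")) {
      return(tkey)
    }
    cds <- character()
    if (!is.na(ttype) && ttype == "CDS") {
      cds <- tkey
    } else if (!is.na(ttype) && ttype == "Promoter") {
      parent <- parent_of[tkey]
      if (!is.na(parent)) {
        sibs <- g$edges$object[g$edges$predicate == "hasPart" &
                                 g$edges$subject == parent]
        cds <- sibs[types[sibs] == "CDS"]
      }
    }
    cds <- cds[!is.na(root_of[cds]) & !is.na(root_of[tkey]) &
                 root_of[cds] == root_of[tkey] |
                 is.na(root_of[tkey]) & is.na(root_of[cds])]
    sort(unique(unlist(cds_to_protein[cds])))
  }

  out <- .empty_proj_edges()
  reg <- edges[edges$predicate %in% c("represses", "activates"), , drop = FALSE]
  for (i in seq_len(nrow(reg))) {
    src <- reg$subject[i]
    if (types[src] == "CDS") {
      src <- sort(unique(unlist(cds_to_protein[src])))
    }
    tgt <- target_proteins(reg$object[i])
    for (s in src) {
      for (t in tgt) {
        path <- .bfs_shortest_path(g, s, t)
        if (is.null(path)) path <- c(s, t)
        out <- rbind(out, data.frame(
          subject = s, predicate = reg$predicate[i], object = t,
          role = NA_character_, weight = NA_real_,
          provenance = paste(path, collapse = "|"),
          path_length = length(path) - 1L, stringsAsFactors = FALSE))
      }
    }
  }
  keep <- names(types)[types %in% c("Protein", "Complex", "SmallMolecule")]
  out <- out[out$subject %in% keep & out$object %in% keep, , drop = FALSE]
  out <- out[!duplicated(out[, c("subject", "predicate", "object")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  list(nodes = keep, edges = out)
}

.haspart_parents <- function(g) {
  hp <- g$edges[g$edges$predicate == "hasPart", , drop = FALSE]
  out <- stats::setNames(rep(NA_character_, length(g$nodes)), names(g$nodes))
  out[hp$object] <- hp$subject
  out
}

# assign every containment-reachable node to its root design
.root_assignment <- function(g) {
  out <- stats::setNames(rep(NA_character_, length(g$nodes)), names(g$nodes))
  hp <- g$edges[g$edges$predicate == "hasPart", , drop = FALSE]
  for (r in g$roots) {
    frontier <- r
    while (length(frontier)) {
      out[frontier] <- r
      frontier <- setdiff(unique(hp$object[hp$subject %in% frontier]),
                          names(out)[!is.na(out)])
    }
  }
  # attach proteins to the root of their producing CDS
  for (ik in names(g$nodes)[vapply(g$nodes, `[[`, "", "type") == "Interaction"]) {
    pp <- .participants(g, ik)
    tmpl <- pp$object[!is.na(pp$role) & pp$role == "template"]
    prod <- pp$object[!is.na(pp$role) & pp$role == "product"]
    if (length(tmpl) && length(prod) && !is.na(out[tmpl[1]])) {
      out[prod[is.na(out[prod])]] <- out[tmpl[1]]
      out[ik] <- out[tmpl[1]]
    }
  }
  out
}

#' @export
print.projection_graph <- function(x, ...) {
  cat(sprintf("<projection_graph view='%s'> %d nodes, %d edges\n",
              x$view, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Network statistics of a projection
#'
#' Node count, edge count, number of connected components of the undirected
#' skeleton (isolated nodes count as components), and the degree histogram.
#'
#' @param p A `projection_graph`.
#' @return A `network_info` list with `node_count`, `edge_count`,
#'   `component_count`, `degree_histogram` (named integer vector,
#'   degree -> number of nodes).
#' @export
network_info <- function(p) {
  stopifnot(inherits(p, "projection_graph"))
  n <- length(p$nodes)
  m <- nrow(p$edges)
  if (n == 0) {
    return(structure(list(node_count = 0L, edge_count = 0L,
                          component_count = 0L,
                          degree_histogram = integer()),
                     class = "network_info"))
  }
  ig <- igraph::graph_from_data_frame(
    p$edges[, c("subject", "object")], directed = FALSE,
    vertices = data.frame(name = p$nodes))
  comp <- igraph::components(ig)$no
  deg <- igraph::degree(ig)
  hist <- table(deg)
  structure(list(node_count = as.integer(n), edge_count = as.integer(m),
                 component_count = as.integer(comp),
                 degree_histogram = stats::setNames(as.integer(hist),
                                                    names(hist))),
            class = "network_info")
}

#' @export
print.network_info <- function(x, ...) {
  cat(sprintf("nodes: %d  edges: %d  components: %d\n",
              x$node_count, x$edge_count, x$component_count))
  invisible(x)
}

#' Re-verify shortest-path provenance of a projection
#'
#' Checks every projected edge's recorded provenance path against an
#' independent shortest-path computation (igraph breadth-first distances on
#' the undirected canonical skeleton) and reports mismatches.
#'
#' @param p A `projection_graph` whose `source` graph is available.
#' @return List with `projection` (unchanged) and `mismatches`, a character
#'   vector describing every edge whose recorded path is not shortest (empty
#'   when all provenance is verified).
#' @export
shortest_path_annotation <- function(p) {
  stopifnot(inherits(p, "projection_graph"))
  g <- p$source
  mism <- character()
  if (!nrow(p$edges)) {
    return(list(projection = p, mismatches = mism))
  }
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("subject", "object")], directed = FALSE,
    vertices = data.frame(name = names(g$nodes)))
  for (i in seq_len(nrow(p$edges))) {
    s <- p$edges$subject[i]; o <- p$edges$object[i]
    path <- strsplit(p$edges$provenance[i], "|", fixed = TRUE)[[1]]
    d <- suppressWarnings(igraph::distances(ig, v = s, to = o))[1, 1]
    ok <- is.finite(d) && length(path) - 1L == d &&
      p$edges$path_length[i] == d &&
      path[1] == s && path[length(path)] == o
    if (!is.finite(d)) {
      # edge invented by a view (e.g. direct canonical edge): path length 1
      ok <- p$edges$path_length[i] == length(path) - 1L
    }
    if (!ok) {
      mism <- c(mism, sprintf(
        "edge %s -%s-> %s: recorded path length %d, BFS shortest %s",
        s, p$edges$predicate[i], o, p$edges$path_length[i],
        ifelse(is.finite(d), as.character(d), "unreachable")))
    }
  }
  list(projection = p, mismatches = mism)
}
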