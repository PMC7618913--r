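# Canonical knowledge-graph data model: typed nodes keyed by absolute URI,
# predicate-labelled directed edges, and the predicate rule table that the
# editor and the projections share.

#' Node type vocabulary
#'
#' The closed vocabulary of node types used in a design graph: genetic part
#' roles (`CDS`, `Promoter`, `RBS`, `Terminator`, `Engineered-Region`),
#' molecular entities (`Protein`, `Complex`, `SmallMolecule`), explicit
#' `Interaction` nodes, `Synonym` nodes created by repository merging, and
#' `Metadata` nodes (e.g. ontology terms).
#'
#' @return Character vector of node type names.
#' @export
node_types <- function() {
  c("CDS", "Promoter", "RBS", "Terminator", "Engineered-Region",
    "Protein", "Complex", "SmallMolecule", "Interaction", "Synonym",
    "Metadata")
}

#' Edge predicate vocabulary
#'
#' @return Character vector of predicate names.
#' @export
edge_predicates <- function() {
  c("hasPart", "hasSequence", "hasParticipant", "interactionType",
    "represses", "activates", "produces", "synonymOf", "similarTo",
    "propertyOf")
}

# node types whose sequences are nucleotide strings
.genetic_part_types <- c("CDS", "Promoter", "RBS", "Terminator",
                         "Engineered-Region")
.entity_types <- c(.genetic_part_types, "Protein", "Complex", "SmallMolecule")

# participation role qualifiers on hasParticipant edges
.active_roles <- c("inhibitor", "stimulator", "template")
.passive_roles <- c("inhibited", "stimulated", "product")

# interaction type labels <-> collapsed predicates
.interaction_predicate_map <- c(repression = "represses",
                                stimulation = "activates",
                                genetic_production = "produces")
.interaction_role_map <- list(
  repression = c(active = "inhibitor", passive = "inhibited"),
  stimulation = c(active = "stimulator", passive = "stimulated"),
  genetic_production = c(active = "template", passive = "product")
)

# SBO terms for interaction types and participant roles, SO terms for parts
.sbo_interaction_terms <- c(
  repression = "https://identifiers.org/SBO:0000169",
  stimulation = "https://identifiers.org/SBO:0000170",
  genetic_production = "https://identifiers.org/SBO:0000589"
)
.sbo_role_terms <- c(
  inhibitor = "https://identifiers.org/SBO:0000020",
  inhibited = "https://identifiers.org/SBO:0000642",
  stimulator = "https://identifiers.org/SBO:0000459",
  stimulated = "https://identifiers.org/SBO:0000643",
  template = "https://identifiers.org/SBO:0000645",
  product = "https://identifiers.org/SBO:0000011"
)
.so_role_terms <- c(
  "CDS" = "https://identifiers.org/SO:0000316",
  "Promoter" = "https://identifiers.org/SO:0000167",
  "RBS" = "https://identifiers.org/SO:0000139",
  "Terminator" = "https://identifiers.org/SO:0000141",
  "Engineered-Region" = "https://identifiers.org/SO:0000804"
)
.entity_type_terms <- c(
  "Protein" = "https://identifiers.org/SBO:0000252",
  "Complex" = "https://identifiers.org/SBO:0000253",
  "SmallMolecule" = "https://identifiers.org/SBO:0000247"
)

#' Normalize a URI used as a node key
#'
#' Node identity is the URI string after dropping any fragment and a single
#' trailing slash, so that serialization variants of the same resource URI
#' collapse to one key.
#'
#' @param uri Character vector of URIs.
#' @return Normalized character vector.
#' @export
normalize_uri <- function(uri) {
  uri <- sub("#.*$", "", uri)
  sub("(?<=.)/$", "", uri, perl = TRUE)
}

#' Test whether a string is a syntactically valid absolute URI
#'
#' Requires a scheme followed by a nonempty authority or path, with no
#' whitespace.
#'
#' @param x Character vector.
#' @return Logical vector.
#' @export
is_absolute_uri <- function(x) {
  !is.na(x) & grepl("^[A-Za-z][A-Za-z0-9+.-]*:[^[:space:]]+$", x) &
    !grepl("[[:space:]]", x)
}

.empty_edges <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), role = character(),
             weight = numeric(), stringsAsFactors = FALSE)
}

#' Create an empty design graph
#'
#' A design graph holds typed nodes keyed by absolute URI, directed
#' predicate-labelled edges (with an optional role qualifier on
#' `hasParticipant` edges and an identity weight on `similarTo` edges), and a
#' set of root keys marking top-level designs.
#'
#' @return An object of class `design_graph`.
#' @export
design_graph <- function() {
  structure(list(nodes = list(), edges = .empty_edges(),
                 roots = character()), class = "design_graph")
}

#' @export
print.design_graph <- function(x, ...) {
  cat(sprintf("<design_graph> %d nodes, %d edges, %d root(s)\n",
              length(x$nodes), nrow(x$edges), length(x$roots)))
  tt <- table(vapply(x$nodes, `[[`, "", "type"))
  if (length(tt)) {
    cat("  node types:",
        paste(sprintf("%s=%d", names(tt), as.integer(tt)), collapse = ", "),
        "\n")
  }
  if (nrow(x$edges)) {
    pt <- table(x$edges$predicate)
    cat("  predicates:",
        paste(sprintf("%s=%d", names(pt), as.integer(pt)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Add a node to a design graph
#'
#' @param g A `design_graph`.
#' @param key Absolute URI (normalized on insertion).
#' @param type One of [node_types()].
#' @param properties Named character vector of string properties (e.g.
#'   `name`, `description`, `sequence`, `source`).
#' @return The updated graph. Adding an existing key with identical type is a
#'   no-op for the node slot (properties are merged, existing values win).
#' @export
graph_add_node <- function(g, key, type, properties = character()) {
  stopifnot(inherits(g, "design_graph"))
  key <- normalize_uri(key)
  if (length(properties) && is.null(names(properties))) {
    stop("properties must be named")
  }
  properties <- vapply(properties, as.character, "")
  if (!is.null(g$nodes[[key]])) {
    old <- g$nodes[[key]]
    keep <- setdiff(names(properties), names(old$properties))
    old$properties <- c(old$properties, properties[keep])
    g$nodes[[key]] <- old
    return(g)
  }
  g$nodes[[key]] <- list(key = key, type = type, properties = properties)
  g
}

#' Add an edge to a design graph
#'
#' Edge identity is the tuple (subject, predicate, role qualifier, object);
#' duplicate edges are not stored. `synonymOf` edges are stored once in the
#' canonical direction (lexicographically smaller subject key).
#'
#' @param g A `design_graph`.
#' @param subject,object Node keys (normalized).
#' @param predicate One of [edge_predicates()].
#' @param role Optional participation role qualifier (for `hasParticipant`).
#' @param weight Optional identity weight in `[0, 1]` (for `similarTo`).
#' @return The updated graph.
#' @export
graph_add_edge <- function(g, subject, predicate, object,
                           role = NA_character_, weight = NA_real_) {
  stopifnot(inherits(g, "design_graph"))
  subject <- normalize_uri(subject)
  object <- normalize_uri(object)
  if (predicate %in% c("synonymOf", "similarTo") && object < subject) {
    tmp <- subject; subject <- object; object <- tmp
  }
  e <- g$edges
  dup <- e$subject == subject & e$predicate == predicate &
    e$object == object &
    (is.na(e$role) & is.na(role) | !is.na(e$role) & !is.na(role) &
       e$role == role)
  if (any(dup)) return(g)
  g$edges <- rbind(e, data.frame(subject = subject, predicate = predicate,
                                 object = object, role = role,
                                 weight = weight, stringsAsFactors = FALSE))
  rownames(g$edges) <- NULL
  g
}

#' Mark a node as a top-level design root
#'
#' @param g A `design_graph`.
#' @param key Node key of an `Engineered-Region` node.
#' @return The updated graph.
#' @export
graph_set_root <- function(g, key) {
  g$roots <- sort(unique(c(g$roots, normalize_uri(key))))
  g
}

.is_dna <- function(s) grepl("^[ACGTUNRYSWKMBDHV]+$", s)
.is_protein <- function(s) grepl("^[ACDEFGHIKLMNPQRSTVWYXBZJUO*]+$", s)

.nodes_reachable_from_roots <- function(g) {
  hp <- g$edges[g$edges$predicate == "hasPart", , drop = FALSE]
  seen <- character()
  frontier <- intersect(g$roots, names(g$nodes))
  while (length(frontier)) {
    seen <- union(seen, frontier)
    nxt <- hp$object[hp$subject %in% frontier]
    frontier <- setdiff(unique(nxt), seen)
  }
  seen
}

#' Validate a design graph against its structural invariants
#'
#' Checks key syntax, node type vocabulary, sequence alphabet consistency,
#' referential closure of edges, `similarTo` weight range, `synonymOf`
#' canonical direction, root typing, and that containment (`hasPart`)
#' restricted to root-reachable nodes forms a forest (no cycles, at most one
#' parent).
#'
#' @param g A `design_graph`.
#' @return Character vector of violation descriptors; empty iff the graph is
#'   valid. Violations are returned, never raised.
#' @export
validate_graph <- function(g) {
  stopifnot(inherits(g, "design_graph"))
  v <- character()
  keys <- names(g$nodes)
  for (k in keys) {
    n <- g$nodes[[k]]
    if (!is_absolute_uri(k)) {
      v <- c(v, sprintf("node %s: key is not a valid absolute URI", k))
    }
    if (!n$type %in% node_types()) {
      v <- c(v, sprintf("node %s: type '%s' not in vocabulary", k, n$type))
    }
    seq <- unname(n$properties["sequence"])
    if (length(seq) == 1 && !is.na(seq)) {
      if (!nzchar(seq)) {
        v <- c(v, sprintf("node %s: sequence property is empty", k))
      } else if (n$type %in% .genetic_part_types && !.is_dna(seq)) {
        v <- c(v, sprintf("node %s: sequence is not valid IUPAC DNA", k))
      } else if (n$type == "Protein" && !.is_protein(seq)) {
        v <- c(v, sprintf("node %s: sequence is not a valid amino-acid string", k))
      }
    }
  }
  e <- g$edges
  for (i in seq_len(nrow(e))) {
    if (!e$subject[i] %in% keys) {
      v <- c(v, sprintf("edge %s -%s-> %s: dangling subject endpoint",
                        e$subject[i], e$predicate[i], e$object[i]))
    }
    if (!e$object[i] %in% keys) {
      v <- c(v, sprintf("edge %s -%s-> %s: dangling object endpoint",
                        e$subject[i], e$predicate[i], e$object[i]))
    }
    if (!e$predicate[i] %in% edge_predicates()) {
      v <- c(v, sprintf("edge %s -%s-> %s: predicate not in vocabulary",
                        e$subject[i], e$predicate[i], e$object[i]))
    }
    if (e$predicate[i] == "similarTo" &&
        (is.na(e$weight[i]) || e$weight[i] < 0 || e$weight[i] > 1)) {
      v <- c(v, sprintf("edge %s -similarTo-> %s: weight not in [0,1]",
                        e$subject[i], e$object[i]))
    }
    if (e$predicate[i] == "synonymOf" && e$object[i] < e$subject[i]) {
      v <- c(v, sprintf("edge %s -synonymOf-> %s: not in canonical direction",
                        e$subject[i], e$object[i]))
    }
  }
  for (r in g$roots) {
    if (!r %in% keys) {
      v <- c(v, sprintf("root %s: not a node of the graph", r))
    } else if (g$nodes[[r]]$type != "Engineered-Region") {
      v <- c(v, sprintf("root %s: not an Engineered-Region node", r))
    }
  }
  reach <- .nodes_reachable_from_roots(g)
  hp <- e[e$predicate == "hasPart" & e$subject %in% reach &
            e$object %in% reach, , drop = FALSE]
  if (nrow(hp)) {
    if (anyDuplicated(hp$object)) {
      dup <- unique(hp$object[duplicated(hp$object)])
      v <- c(v, sprintf("node %s: multiple hasPart parents (containment not a forest)",
                        dup))
    }
    ig <- igraph::graph_from_data_frame(hp[, c("subject", "object")],
                                        directed = TRUE)
    if (!igraph::is_dag(ig)) {
      v <- c(v, "hasPart containment contains a cycle")
    }
  }
  v
}

# ---- predicate rule table ----------------------------------------------

.default_rule_table <- function() {
  list(
    list(predicate = "produces",
         views = c("interaction", "full"),
         allowed_subject_types = "CDS",
         allowed_object_types = "Protein",
         expansion = "interaction"),
    list(predicate = "represses",
         views = c("interaction", "protein_network", "full"),
         allowed_subject_types = c("Protein", "Complex", "SmallMolecule"),
         allowed_object_types = c("Promoter", "CDS", "Engineered-Region"),
         expansion = "interaction"),
    list(predicate = "activates",
         views = c("interaction", "protein_network", "full"),
         allowed_subject_types = c("Protein", "Complex", "SmallMolecule"),
         allowed_object_types = c("Promoter", "CDS", "Engineered-Region"),
         expansion = "interaction"),
    list(predicate = "hasPart",
         views = c("hierarchy", "full"),
         allowed_subject_types = "Engineered-Region",
         allowed_object_types = .genetic_part_types,
         expansion = "direct"),
    list(predicate = "synonymOf",
         views = "full",
         allowed_subject_types = node_types(),
         allowed_object_types = node_types(),
         expansion = "direct"),
    list(predicate = "similarTo",
         views = "full",
         allowed_subject_types = .genetic_part_types,
         allowed_object_types = .genetic_part_types,
         expansion = "direct"),
    list(predicate = "propertyOf",
         views = "full",
         allowed_subject_types = "Metadata",
         allowed_object_types = node_types(),
         expansion = "direct")
  )
}

.registered_views <- c("full", "hierarchy", "interaction_verbose",
                       "interaction", "protein_network")

#' Predicate rules available in a projection view
#'
#' Each rule names a predicate, the node types allowed as its subject and
#' object, and the canonical expansion used by [expand_edit()]. The rule set
#' depends on the view: the interaction view offers repression, activation
#' and genetic production; the hierarchy view offers containment only. The
#' shipped rule for genetic production requires a coding-sequence subject and
#' a protein object.
#'
#' @param view_name A registered view name (`full`, `hierarchy`,
#'   `interaction_verbose`, `interaction`, `protein_network`).
#' @param rules Optional rule table (see [load_rule_table()]); defaults to
#'   the built-in table.
#' @return List of predicate rules applicable in the view.
#' @export
predicate_rules <- function(view_name, rules = NULL) {
  if (!view_name %in% .registered_views) {
    stop(sprintf("unregistered view '%s'", view_name))
  }
  if (is.null(rules)) rules <- .default_rule_table()
  Filter(function(r) view_name %in% r$views, rules)
}

#' Load a predicate rule table from a JSON config file
#'
#' The file holds an array of objects with fields `predicate`, `views`,
#' `allowed_subject_types`, `allowed_object_types` and `expansion`
#' (`"interaction"` or `"direct"`), so deployments can extend the predicate
#' vocabulary without code changes.
#'
#' @param path Path to a JSON file.
#' @return A rule table usable as the `rules` argument of
#'   [predicate_rules()].
#' @export
load_rule_table <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    list(predicate = unlist(r$predicate)[1],
         views = unlist(r$views),
         allowed_subject_types = unlist(r$allowed_subject_types),
         allowed_object_types = unlist(r$allowed_object_types),
         expansion = unlist(r$expansion)[1])
  })
}
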