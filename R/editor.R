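# Graph-level editing: node-key validation with candidate resolution by
# name and sequence matching, type-rule enforcement per projection view,
# and expansion of projected edits into canonical graph structure.

#' Create a resolver for node-key validation
#'
#' Under the `offline_syntactic` policy only URI syntax is checked and the
#' corpus is never consulted; under `corpus_lookup` a key is valid only if
#' it resolves to a record of the lookup corpus, and invalid keys are
#' matched against the corpus by name and sequence to propose candidates.
#'
#' @param corpus Optional part-record data frame (see [part_records()]).
#' @param policy `offline_syntactic` or `corpus_lookup`.
#' @param candidate_threshold Minimum match score for candidates.
#' @return A `resolver` object.
#' @export
resolver <- function(corpus = NULL,
                     policy = c("offline_syntactic", "corpus_lookup"),
                     candidate_threshold = cg_config()[["candidate.threshold"]]) {
  policy <- match.arg(policy)
  if (policy == "corpus_lookup" && is.null(corpus)) {
    stop("corpus_lookup policy requires a corpus")
  }
  structure(list(corpus = corpus, policy = policy,
                 candidate_threshold = candidate_threshold),
            class = "resolver")
}

#' Normalized Levenshtein similarity between two names
#'
#' One minus the edit distance divided by the longer length, on lowercased
#' strings; 1 for identical names, 0 when every position differs.
#'
#' @param a,b Character strings.
#' @return Similarity in `[0, 1]`.
#' @export
name_similarity <- function(a, b) {
  a <- tolower(a); b <- tolower(b)
  if (!nchar(a) && !nchar(b)) return(1)
  d <- utils::adist(a, b)[1, 1]
  1 - d / max(nchar(a), nchar(b))
}

#' Validate a node key and propose candidates
#'
#' A key is valid iff it is a well-formed absolute URI and, under the
#' `corpus_lookup` policy, present in the resolver corpus (after key
#' normalization). For invalid keys the corpus records are ranked by the
#' maximum of name similarity (against `name`, falling back to the last
#' path segment of the key) and sequence identity (when `sequence` is
#' given); records scoring at or above the candidate threshold are
#' returned in descending score order, ties broken by key.
#'
#' @param key Key string to validate.
#' @param r A [resolver()].
#' @param name Optional query name for matching.
#' @param sequence Optional query sequence for matching.
#' @return List with `valid` (logical) and `candidates` (data frame:
#'   `key`, `score`, `basis`).
#' @export
validate_node_key <- function(key, r, name = NULL, sequence = NULL) {
  stopifnot(inherits(r, "resolver"))
  no_cand <- data.frame(key = character(), score = numeric(),
                        basis = character(), stringsAsFactors = FALSE)
  syntactic <- is_absolute_uri(key)
  if (r$policy == "offline_syntactic") {
    return(list(valid = unname(syntactic), candidates = no_cand))
  }
  nkey <- normalize_uri(key)
  known <- nkey %in% normalize_uri(r$corpus$key)
  if (syntactic && known) {
    return(list(valid = TRUE, candidates = no_cand))
  }
  qname <- name
  if (is.null(qname)) {
    segs <- strsplit(nkey, "/", fixed = TRUE)[[1]]
    segs <- segs[nzchar(segs)]
    qname <- if (length(segs)) segs[length(segs)] else key
  }
  cand <- data.frame(key = r$corpus$key,
                     score = NA_real_, basis = NA_character_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cand))) {
    ns <- name_similarity(qname, r$corpus$name[i])
    ss <- -1
    if (!is.null(sequence) && nzchar(sequence) &&
        nzchar(r$corpus$sequence[i])) {
      ss <- pairwise_identity(sequence, r$corpus$sequence[i])
    }
    if (ss >= ns) {
      cand$score[i] <- ss; cand$basis[i] <- "sequence"
    } else {
      cand$score[i] <- ns; cand$basis[i] <- "name"
    }
  }
  cand <- cand[cand$score >= r$candidate_threshold, , drop = FALSE]
  cand <- cand[order(-cand$score, cand$key), , drop = FALSE]
  rownames(cand) <- NULL
  list(valid = FALSE, candidates = cand)
}

.edit_request <- function(kind, payload, status, reasons = character(),
                          candidates = NULL, triples_added = NULL) {
  structure(list(kind = kind, payload = payload, status = status,
                 reasons = reasons, candidates = candidates,
                 triples_added = triples_added),
            class = "edit_request")
}

#' @export
print.edit_request <- function(x, ...) {
  cat(sprintf("<edit_request %s> status: %s\n", x$kind, x$status))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = "; "),
                             "\n")
  if (!is.null(x$triples_added) && nrow(x$triples_added)) {
    cat(sprintf("  %d canonical triple(s) added\n", nrow(x$triples_added)))
  }
  invisible(x)
}

#' Add a node to a design through the editor
#'
#' Validates the key through the resolver (unless `force = TRUE`), rejects
#' duplicate keys and unknown types, and otherwise adds the node with its
#' properties. Rejected requests carry at least one reason; when the key
#' fails resolution, the request carries the ranked candidate keys so a
#' caller can accept one instead.
#'
#' @param g A `design_graph`.
#' @param key Node key (absolute URI).
#' @param node_type One of [node_types()].
#' @param properties Named character vector of properties.
#' @param r A [resolver()]; defaults to offline syntactic checking.
#' @param force Accept the key even if resolution fails.
#' @return List with `graph` (updated or unchanged) and `request`
#'   (an `edit_request` with status `applied` or `rejected`).
#' @export
add_node <- function(g, key, node_type, properties = character(),
                     r = resolver(), force = FALSE) {
  stopifnot(inherits(g, "design_graph"))
  payload <- list(key = key, node_type = node_type, properties = properties)
  vk <- validate_node_key(key, r,
                          name = unname(properties["name"]) %NA% NULL,
                          sequence = unname(properties["sequence"]) %NA% NULL)
  reasons <- character()
  if (!vk$valid && !force) {
    reasons <- c(reasons, sprintf("key '%s' does not resolve to a valid resource", key))
  }
  if (!node_type %in% node_types()) {
    reasons <- c(reasons, sprintf("unknown node type '%s'", node_type))
  }
  if (normalize_uri(key) %in% names(g$nodes)) {
    reasons <- c(reasons, "node exists")
  }
  if (length(reasons)) {
    return(list(graph = g,
                request = .edit_request("add_node", payload, "rejected",
                                        reasons, candidates = vk$candidates)))
  }
  g2 <- graph_add_node(g, key, node_type, properties)
  viol <- validate_graph(g2)
  if (length(viol)) {
    return(list(graph = g,
                request = .edit_request("add_node", payload, "rejected",
                                        viol, candidates = vk$candidates)))
  }
  triples <- data.frame(subject = normalize_uri(key), predicate = "rdf:type",
                        object = node_type, stringsAsFactors = FALSE)
  list(graph = g2,
       request = .edit_request("add_node", payload, "applied",
                               triples_added = triples))
}

`%NA%` <- function(x, y) if (length(x) != 1 || is.na(x)) y else x

#' Add a projected edge through the editor
#'
#' The predicate must be offered by the current view's rule table and the
#' endpoint node types must satisfy the rule (for genetic production the
#' subject must be a coding sequence and the object a protein). Valid
#' requests are expanded into canonical graph structure with
#' [expand_edit()], so that re-projecting the view shows the new edge.
#'
#' @param g A `design_graph`.
#' @param view_name The projection view the edit is expressed against.
#' @param subject,object Keys of existing nodes.
#' @param predicate Predicate name offered in the view.
#' @param namespace Namespace for minted interaction keys.
#' @param rules Optional predicate rule table.
#' @return List with `graph` and `request` (see [add_node()]).
#' @export
add_edge <- function(g, view_name, subject, predicate, object,
                     namespace = cg_config()[["mint.namespace"]],
                     rules = NULL) {
  stopifnot(inherits(g, "design_graph"))
  payload <- list(view = view_name, subject = subject,
                  predicate = predicate, object = object)
  subject <- normalize_uri(subject); object <- normalize_uri(object)
  vr <- predicate_rules(view_name, rules = rules)
  rule <- Filter(function(r) r$predicate == predicate, vr)
  reasons <- character()
  if (!length(rule)) {
    reasons <- c(reasons, sprintf(
      "predicate '%s' is not available in view '%s'", predicate, view_name))
    rule <- list(NULL)
  }
  if (!subject %in% names(g$nodes)) {
    reasons <- c(reasons, sprintf("unknown subject node %s", subject))
  }
  if (!object %in% names(g$nodes)) {
    reasons <- c(reasons, sprintf("unknown object node %s", object))
  }
  if (!length(reasons)) {
    rl <- rule[[1]]
    st <- g$nodes[[subject]]$type
    ot <- g$nodes[[object]]$type
    if (!st %in% rl$allowed_subject_types) {
      reasons <- c(reasons, sprintf(
        "rule %s: subject type %s not allowed (requires %s)", predicate, st,
        paste(rl$allowed_subject_types, collapse = "/")))
    }
    if (!ot %in% rl$allowed_object_types) {
      reasons <- c(reasons, sprintf(
        "rule %s: object type %s not allowed (requires %s)", predicate, ot,
        paste(rl$allowed_object_types, collapse = "/")))
    }
  }
  if (length(reasons)) {
    return(list(graph = g,
                request = .edit_request("add_edge", payload, "rejected",
                                        reasons)))
  }
  req <- .edit_request("add_edge", payload, "validated")
  expand_edit(req, g, namespace = namespace, rules = rules)
}

#' Expand a validated projected edit into canonical triples
#'
#' Projected edges may not correspond to single canonical triples; each
#' rule carries an expansion template. Interaction-view predicates mint a
#' fresh `Interaction` node (deterministic counter under the configured
#' namespace), an `interactionType` triple (`represses` to repression,
#' `activates` to stimulation, `produces` to genetic production) and two
#' role-qualified `hasParticipant` triples (active role on the subject,
#' passive on the object). Hierarchy-view containment adds the `hasPart`
#' triple directly after checking that no containment cycle (or second
#' parent) would result; full-view edits add the raw triple.
#'
#' @param e A validated `edit_request` of kind `add_edge`.
#' @param g A `design_graph`.
#' @param namespace Namespace for minted interaction keys.
#' @param rules Optional predicate rule table.
#' @return List with `graph` and `request`; the applied request records the
#'   canonical triples it created.
#' @export
expand_edit <- function(e, g, namespace = cg_config()[["mint.namespace"]],
                        rules = NULL) {
  stopifnot(inherits(e, "edit_request"), e$kind == "add_edge",
            e$status == "validated")
  p <- e$payload
  vr <- predicate_rules(p$view, rules = rules)
  rule <- Filter(function(r) r$predicate == p$predicate, vr)[[1]]
  subject <- normalize_uri(p$subject); object <- normalize_uri(p$object)
  before <- nrow(g$edges)
  # the full view mirrors the canonical graph, so its edits need no
  # expansion; interaction-view predicates expand through an Interaction node
  if (identical(rule$expansion, "interaction") && p$view != "full") {
    label <- names(.interaction_predicate_map)[
      .interaction_predicate_map == p$predicate]
    n_mint <- sum(startsWith(names(g$nodes),
                             paste0(namespace, "/interaction_")))
    ikey <- sprintf("%s/interaction_%d", namespace, n_mint + 1L)
    term <- unname(.sbo_interaction_terms[label])
    roles <- .interaction_role_map[[label]]
    g2 <- graph_add_node(g, ikey, "Interaction")
    g2 <- graph_add_node(g2, term, "Metadata",
                         c(name = gsub("_", " ", label)))
    g2 <- graph_add_edge(g2, ikey, "interactionType", term)
    g2 <- graph_add_edge(g2, ikey, "hasParticipant", subject,
                         role = unname(roles["active"]))
    g2 <- graph_add_edge(g2, ikey, "hasParticipant", object,
                         role = unname(roles["passive"]))
  } else {
    g2 <- graph_add_edge(g, subject, p$predicate, object)
  }
  viol <- validate_graph(g2)
  if (length(viol)) {
    e$status <- "rejected"; e$reasons <- viol
    return(list(graph = g, request = e))
  }
  added <- g2$edges[seq_len(nrow(g2$edges)) > before, , drop = FALSE]
  e$status <- "applied"
  e$triples_added <- added
  list(graph = g2, request = e)
}
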