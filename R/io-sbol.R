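# SBOL read/write. The canonical serialization is SBOL3 as RDF/XML:
# Components typed with SO roles (parts) or SBO terms (proteins, complexes,
# small molecules), SubComponent features for containment, Interactions with
# role-qualified Participations, Sequence objects for sequence properties.
# Tool-specific relations that SBOL does not model (synonym links,
# identity-weighted similarity, node-type annotations) live under a
# companion namespace so that read(write(g)) is graph-isomorphic to g.
# SBOL2 documents are read-only and converted on ingest.

.ns_rdf <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
.ns_sbol3 <- "http://sbols.org/v3#"
.ns_sbol2 <- "http://sbols.org/v2#"
.ns_cg <- "https://circuitgraph.local/ns#"

.sbol3_dna_type <- "https://identifiers.org/SBO:0000251"

# ---- generic RDF/XML triple extraction ---------------------------------

.rdf_triples <- function(doc) {
  ns <- xml2::xml_ns(doc)
  expand <- function(pname) {
    parts <- strsplit(pname, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2 && parts[1] %in% names(ns)) {
      paste0(ns[[parts[1]]], parts[2])
    } else {
      pname
    }
  }
  rows <- list()
  add <- function(s, p, o, lit) {
    rows[[length(rows) + 1L]] <<- list(s = s, p = p, o = o, lit = lit)
  }
  get_attr <- function(el, local) {
    a <- xml2::xml_attr(el, local)
    if (is.na(a)) {
      attrs <- xml2::xml_attrs(el)
      hit <- grep(paste0("(^|:)", local, "$"), names(attrs))
      a <- if (length(hit)) attrs[[hit[1]]] else NA_character_
    }
    a
  }
  walk_subject <- function(el) {
    s <- get_attr(el, "about")
    if (is.na(s)) s <- paste0("_:b", xml2::xml_path(el))
    type <- expand(xml2::xml_name(el, ns))
    if (type != paste0(.ns_rdf, "Description")) {
      add(s, paste0(.ns_rdf, "type"), type, FALSE)
    }
    for (ch in xml2::xml_children(el)) {
      pred <- expand(xml2::xml_name(ch, ns))
      res <- get_attr(ch, "resource")
      if (!is.na(res)) {
        add(s, pred, res, FALSE)
      } else if (xml2::xml_length(ch) > 0) {
        for (nested in xml2::xml_children(ch)) {
          add(s, pred, walk_subject(nested), FALSE)
        }
      } else {
        add(s, pred, xml2::xml_text(ch), TRUE)
      }
    }
    s
  }
  for (el in xml2::xml_children(xml2::xml_root(doc))) walk_subject(el)
  if (!length(rows)) {
    return(data.frame(s = character(), p = character(), o = character(),
                      lit = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
}

.tr_objects <- function(tr, s, p) tr$o[tr$s == s & tr$p == p]
.tr_subjects <- function(tr, p, o) tr$s[tr$p == p & tr$o == o]

# ---- SBOL3 writer ------------------------------------------------------

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.is_ncname <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", x)

#' Serialize a design graph as an SBOL3 (RDF/XML) document
#'
#' The graph must satisfy every structural invariant; otherwise the writer
#' refuses to serialize and returns the violation list. The output is
#' byte-stable for a fixed graph (nodes and statements written in sorted
#' order), and `read_design()` of the output is graph-isomorphic to the
#' input on keys, types, predicates and properties.
#'
#' @param g A `design_graph`.
#' @param path Optional output file path; when `NULL` the document text is
#'   returned.
#' @return The serialized document text (invisibly when written to a file).
#'   If the graph is invalid, an error of class `circuitgraph_invalid_graph`
#'   carrying the violations in its `violations` field is raised.
#' @export
write_sbol <- function(g, path = NULL) {
  stopifnot(inherits(g, "design_graph"))
  viol <- validate_graph(g)
  if (length(viol)) {
    cond <- structure(class = c("circuitgraph_invalid_graph", "error",
                                "condition"),
                      list(message = paste0(
                        "graph violates invariants; refusing to serialize:\n",
                        paste(" -", viol, collapse = "\n")),
                        call = NULL, violations = viol))
    stop(cond)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<rdf:RDF xmlns:rdf=\"%s\" xmlns:sbol=\"%s\" ",
                   "xmlns:cg=\"%s\">"), .ns_rdf, .ns_sbol3, .ns_cg))
  e <- g$edges
  desc_open <- function(key) sprintf("  <rdf:Description rdf:about=\"%s\">",
                                     .xml_escape(key))
  res_line <- function(pred, uri) sprintf("    <%s rdf:resource=\"%s\"/>",
                                          pred, .xml_escape(uri))
  lit_line <- function(pred, val) sprintf("    <%s>%s</%s>", pred,
                                          .xml_escape(val), pred)
  sim_count <- 0L
  for (key in sort(names(g$nodes))) {
    n <- g$nodes[[key]]
    body <- character()
    props <- n$properties
    if (n$type == "Interaction") {
      body <- c(body, res_line("rdf:type", paste0(.ns_sbol3, "Interaction")))
      itypes <- e$object[e$predicate == "interactionType" & e$subject == key]
      for (t in sort(itypes)) body <- c(body, res_line("sbol:type", t))
      pp <- e[e$predicate == "hasParticipant" & e$subject == key, ,
              drop = FALSE]
      pp <- pp[order(pp$object, pp$role), , drop = FALSE]
      for (i in seq_len(nrow(pp))) {
        body <- c(body, res_line("sbol:hasParticipation",
                                 sprintf("%s/participation_%d", key, i)))
      }
    } else if (n$type %in% .genetic_part_types) {
      body <- c(body, res_line("rdf:type", paste0(.ns_sbol3, "Component")),
                res_line("sbol:type", .sbol3_dna_type),
                res_line("sbol:role", unname(.so_role_terms[n$type])))
    } else if (n$type %in% c("Protein", "Complex", "SmallMolecule")) {
      body <- c(body, res_line("rdf:type", paste0(.ns_sbol3, "Component")),
                res_line("sbol:type", unname(.entity_type_terms[n$type])))
    }
    body <- c(body, lit_line("cg:nodeType", n$type))
    if (key %in% g$roots) body <- c(body, lit_line("cg:root", "true"))
    for (pn in sort(names(props))) {
      val <- unname(props[pn])
      if (pn == "name") {
        body <- c(body, lit_line("sbol:name", val))
      } else if (pn == "description") {
        body <- c(body, lit_line("sbol:description", val))
      } else if (pn == "sequence") {
        body <- c(body, res_line("sbol:hasSequence",
                                 paste0(key, "_sequence")))
      } else if (.is_ncname(pn)) {
        body <- c(body, lit_line(paste0("cg:", pn), val))
      } else {
        cg_log("warn", "io", sprintf(
          "node %s: property '%s' is not serializable as XML; dropped",
          key, pn))
      }
    }
    # subcomponent features for containment
    kids <- sort(e$object[e$predicate == "hasPart" & e$subject == key])
    for (i in seq_along(kids)) {
      body <- c(body, res_line("sbol:hasFeature",
                               sprintf("%s/SubComponent_%d", key, i)))
    }
    # companion-namespace relations
    for (pred in c("synonymOf", "propertyOf", "represses", "activates",
                   "produces")) {
      objs <- sort(e$object[e$predicate == pred & e$subject == key])
      for (o in objs) body <- c(body, res_line(paste0("cg:", pred), o))
    }
    sims <- e[e$predicate == "similarTo" & e$subject == key, , drop = FALSE]
    sims <- sims[order(sims$object), , drop = FALSE]
    for (i in seq_len(nrow(sims))) {
      sim_count <- sim_count + 1L
      body <- c(body, res_line("cg:hasSimilarity",
                               sprintf("%s_similarity_%d", key, i)))
    }
    lines <- c(lines, desc_open(key), body, "  </rdf:Description>")
    # dependent objects: sequence, participations, similarity records
    seqv <- unname(props["sequence"])
    if (length(seqv) == 1 && !is.na(seqv)) {
      lines <- c(lines, desc_open(paste0(key, "_sequence")),
                 res_line("rdf:type", paste0(.ns_sbol3, "Sequence")),
                 lit_line("sbol:elements", seqv),
                 "  </rdf:Description>")
    }
    if (n$type == "Interaction") {
      pp <- e[e$predicate == "hasParticipant" & e$subject == key, ,
              drop = FALSE]
      pp <- pp[order(pp$object, pp$role), , drop = FALSE]
      for (i in seq_len(nrow(pp))) {
        pkey <- sprintf("%s/participation_%d", key, i)
        plines <- c(desc_open(pkey),
                    res_line("rdf:type", paste0(.ns_sbol3, "Participation")))
        if (!is.na(pp$role[i])) {
          plines <- c(plines, res_line("sbol:role",
                                       unname(.sbo_role_terms[pp$role[i]])))
        }
        lines <- c(lines, plines,
                   res_line("sbol:participant", pp$object[i]),
                   "  </rdf:Description>")
      }
    }
    for (i in seq_len(nrow(sims))) {
      skey <- sprintf("%s_similarity_%d", key, i)
      lines <- c(lines, desc_open(skey),
                 res_line("cg:target", sims$object[i]),
                 lit_line("cg:identity",
                          format(sims$weight[i], digits = 15)),
                 "  </rdf:Description>")
    }
    kids <- sort(e$object[e$predicate == "hasPart" & e$subject == key])
    for (i in seq_along(kids)) {
      skey <- sprintf("%s/SubComponent_%d", key, i)
      lines <- c(lines, desc_open(skey),
                 res_line("rdf:type", paste0(.ns_sbol3, "SubComponent")),
                 res_line("sbol:instanceOf", kids[i]),
                 "  </rdf:Description>")
    }
  }
  lines <- c(lines, "</rdf:RDF>", "")
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

# ---- SBOL3 reader ------------------------------------------------------

.sbol3_node_type_from_triples <- function(tr, s) {
  nt <- tr$o[tr$s == s & tr$p == paste0(.ns_cg, "nodeType")]
  if (length(nt)) return(nt[1])
  rtypes <- .tr_objects(tr, s, paste0(.ns_rdf, "type"))
  if (paste0(.ns_sbol3, "Interaction") %in% rtypes) return("Interaction")
  if (paste0(.ns_sbol3, "Component") %in% rtypes) {
    roles <- .tr_objects(tr, s, paste0(.ns_sbol3, "role"))
    hit <- names(.so_role_terms)[.so_role_terms %in% roles]
    if (length(hit)) return(hit[1])
    stypes <- .tr_objects(tr, s, paste0(.ns_sbol3, "type"))
    hit <- names(.entity_type_terms)[.entity_type_terms %in% stypes]
    if (length(hit)) return(hit[1])
    return("Engineered-Region")
  }
  NA_character_
}

.read_sbol3_triples <- function(tr) {
  g <- design_graph()
  subjects <- unique(tr$s)
  aux_types <- paste0(.ns_sbol3,
                      c("Sequence", "Participation", "SubComponent"))
  is_aux <- vapply(subjects, function(s) {
    any(.tr_objects(tr, s, paste0(.ns_rdf, "type")) %in% aux_types) ||
      length(.tr_objects(tr, s, paste0(.ns_cg, "target"))) > 0
  }, TRUE)
  main <- subjects[!is_aux]
  node_subjects <- main[!is.na(vapply(main, function(s)
    .sbol3_node_type_from_triples(tr, s), ""))]
  for (s in sort(node_subjects)) {
    type <- .sbol3_node_type_from_triples(tr, s)
    props <- character()
    nm <- tr$o[tr$s == s & tr$p == paste0(.ns_sbol3, "name") & tr$lit]
    if (length(nm)) props["name"] <- nm[1]
    de <- tr$o[tr$s == s & tr$p == paste0(.ns_sbol3, "description") & tr$lit]
    if (length(de)) props["description"] <- de[1]
    sq <- .tr_objects(tr, s, paste0(.ns_sbol3, "hasSequence"))
    if (length(sq)) {
      el <- tr$o[tr$s == sq[1] & tr$p == paste0(.ns_sbol3, "elements")]
      if (length(el)) props["sequence"] <- el[1]
    }
    cgp <- tr[tr$s == s & startsWith(tr$p, .ns_cg) & tr$lit, , drop = FALSE]
    for (i in seq_len(nrow(cgp))) {
      pn <- sub(.ns_cg, "", cgp$p[i], fixed = TRUE)
      if (!pn %in% c("nodeType", "root")) props[pn] <- cgp$o[i]
    }
    g <- graph_add_node(g, s, type, props)
    if (any(tr$s == s & tr$p == paste0(.ns_cg, "root") & tr$o == "true")) {
      g <- graph_set_root(g, s)
    }
  }
  keyset <- names(g$nodes)
  for (s in sort(node_subjects)) {
    skey <- normalize_uri(s)
    # containment via SubComponent features
    for (f in .tr_objects(tr, s, paste0(.ns_sbol3, "hasFeature"))) {
      inst <- .tr_objects(tr, f, paste0(.ns_sbol3, "instanceOf"))
      if (length(inst)) g <- graph_add_edge(g, skey, "hasPart", inst[1])
    }
    if (g$nodes[[skey]]$type == "Interaction") {
      for (t in .tr_objects(tr, s, paste0(.ns_sbol3, "type"))) {
        label <- names(.sbo_interaction_terms)[.sbo_interaction_terms == t]
        if (length(label)) {
          g <- graph_add_node(g, t, "Metadata",
                              c(name = gsub("_", " ", label[1])))
          g <- graph_add_edge(g, skey, "interactionType", t)
        }
      }
      for (pt in .tr_objects(tr, s, paste0(.ns_sbol3, "hasParticipation"))) {
        part <- .tr_objects(tr, pt, paste0(.ns_sbol3, "participant"))
        roles <- .tr_objects(tr, pt, paste0(.ns_sbol3, "role"))
        role <- NA_character_
        hit <- names(.sbo_role_terms)[.sbo_role_terms %in% roles]
        if (length(hit)) role <- hit[1]
        if (length(part)) {
          g <- graph_add_edge(g, skey, "hasParticipant", part[1],
                              role = role)
        }
      }
    }
    for (pred in c("synonymOf", "propertyOf", "represses", "activates",
                   "produces")) {
      for (o in .tr_objects(tr, s, paste0(.ns_cg, pred))) {
        g <- graph_add_edge(g, skey, pred, o)
      }
    }
    for (sim in .tr_objects(tr, s, paste0(.ns_cg, "hasSimilarity"))) {
      tgt <- .tr_objects(tr, sim, paste0(.ns_cg, "target"))
      idy <- tr$o[tr$s == sim & tr$p == paste0(.ns_cg, "identity")]
      if (length(tgt)) {
        g <- graph_add_edge(g, skey, "similarTo", tgt[1],
                            weight = as.numeric(idy[1]))
      }
    }
  }
  # fallback root inference for documents without explicit root markers:
  # engineered regions that contain parts and are not contained themselves
  if (!length(g$roots)) {
    hp <- g$edges[g$edges$predicate == "hasPart", , drop = FALSE]
    cand <- setdiff(unique(hp$subject), unique(hp$object))
    cand <- cand[vapply(cand, function(k)
      g$nodes[[k]]$type == "Engineered-Region", TRUE)]
    for (r in cand) g <- graph_set_root(g, r)
  }
  g
}

# ---- SBOL2 reader (read-only subset) -----------------------------------

.read_sbol2_triples <- function(tr) {
  g <- design_graph()
  p2 <- function(x) paste0(.ns_sbol2, x)
  cdefs <- unique(.tr_subjects(tr, paste0(.ns_rdf, "type"),
                               p2("ComponentDefinition")))
  sbol2_dna <- "http://www.biopax.org/release/biopax-level3.owl#DnaRegion"
  sbol2_protein <- "http://www.biopax.org/release/biopax-level3.owl#Protein"
  so_compact <- stats::setNames(names(.so_role_terms),
                                sub("https://identifiers.org/SO:",
                                    "http://identifiers.org/so/SO:",
                                    .so_role_terms))
  for (s in sort(cdefs)) {
    roles <- .tr_objects(tr, s, p2("role"))
    types <- .tr_objects(tr, s, p2("type"))
    nt <- "Engineered-Region"
    hit <- names(.so_role_terms)[.so_role_terms %in% roles]
    if (!length(hit)) hit <- unname(so_compact[roles[roles %in%
                                                       names(so_compact)]])
    if (length(hit)) {
      nt <- hit[1]
    } else if (sbol2_protein %in% types) {
      nt <- "Protein"
    }
    props <- character()
    nm <- tr$o[tr$s == s & tr$p == p2("displayId") & tr$lit]
    if (length(nm)) props["name"] <- nm[1]
    sq <- .tr_objects(tr, s, p2("sequence"))
    if (length(sq)) {
      el <- tr$o[tr$s == sq[1] & tr$p == p2("elements")]
      if (length(el)) props["sequence"] <- el[1]
    }
    g <- graph_add_node(g, s, nt, props)
  }
  for (s in sort(cdefs)) {
    for (c2 in .tr_objects(tr, s, p2("component"))) {
      def <- .tr_objects(tr, c2, p2("definition"))
      if (length(def)) {
        g <- graph_add_edge(g, normalize_uri(s), "hasPart", def[1])
      }
    }
  }
  inters <- unique(.tr_subjects(tr, paste0(.ns_rdf, "type"),
                                p2("Interaction")))
  sbo2to3 <- function(u) sub("http://identifiers.org/biomodels.sbo/",
                             "https://identifiers.org/", u, fixed = TRUE)
  for (s in sort(inters)) {
    g <- graph_add_node(g, s, "Interaction")
    for (t in .tr_objects(tr, s, p2("type"))) {
      t3 <- sbo2to3(t)
      label <- names(.sbo_interaction_terms)[.sbo_interaction_terms == t3]
      if (length(label)) {
        g <- graph_add_node(g, t3, "Metadata",
                            c(name = gsub("_", " ", label[1])))
        g <- graph_add_edge(g, normalize_uri(s), "interactionType", t3)
      }
    }
    for (pt in .tr_objects(tr, s, p2("participation"))) {
      part <- .tr_objects(tr, pt, p2("participant"))
      if (length(part)) {
        # participant may indirect through a FunctionalComponent
        def <- .tr_objects(tr, part[1], p2("definition"))
        if (length(def)) part <- def
      }
      roles <- sbo2to3(.tr_objects(tr, pt, p2("role")))
      role <- NA_character_
      hit <- names(.sbo_role_terms)[.sbo_role_terms %in% roles]
      if (length(hit)) role <- hit[1]
      if (length(part) && part[1] %in% names(g$nodes)) {
        g <- graph_add_edge(g, normalize_uri(s), "hasParticipant", part[1],
                            role = role)
      } else if (length(part)) {
        g <- graph_add_node(g, part[1], "Protein")
        g <- graph_add_edge(g, normalize_uri(s), "hasParticipant", part[1],
                            role = role)
      }
    }
  }
  hp <- g$edges[g$edges$predicate == "hasPart", , drop = FALSE]
  cand <- setdiff(unique(hp$subject), unique(hp$object))
  cand <- cand[vapply(cand, function(k)
    g$nodes[[k]]$type == "Engineered-Region", TRUE)]
  for (r in cand) g <- graph_set_root(g, r)
  g
}
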