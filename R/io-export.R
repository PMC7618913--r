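# Export of projection graphs to standard graph exchange formats:
# GraphML, node-link JSON and edge-list CSV. Output is byte-stable for a
# fixed projection (nodes and edges written in sorted order); node types
# and per-edge provenance (path length, canonical path) are carried as
# attributes. GraphML and JSON exports can be re-imported for checking.

#' Export a projection to a graph exchange format
#'
#' @param p A `projection_graph`.
#' @param format One of `graphml`, `json` (node-link), `csv` (edge list).
#' @param path Optional output file path; when `NULL` the text is returned.
#' @return The serialized text (invisibly when written to a file).
#' @export
export_projection <- function(p, format = c("graphml", "json", "csv"),
                              path = NULL) {
  stopifnot(inherits(p, "projection_graph"))
  if (!is.character(format) || !format[1] %in% c("graphml", "json", "csv")) {
    stop(sprintf("unknown export format '%s'", format[1]))
  }
  format <- match.arg(format)
  p <- .proj_sort(p)
  text <- switch(format,
                 graphml = .export_graphml(p),
                 json = .export_json(p),
                 csv = .export_csv(p))
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

.export_graphml <- function(p) {
  esc <- .xml_escape
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"d0\" for=\"node\" attr.name=\"node_type\" attr.type=\"string\"/>",
    "  <key id=\"d1\" for=\"edge\" attr.name=\"predicate\" attr.type=\"string\"/>",
    "  <key id=\"d2\" for=\"edge\" attr.name=\"path_length\" attr.type=\"int\"/>",
    "  <key id=\"d3\" for=\"edge\" attr.name=\"provenance\" attr.type=\"string\"/>",
    "  <key id=\"d4\" for=\"edge\" attr.name=\"role\" attr.type=\"string\"/>",
    "  <key id=\"d5\" for=\"edge\" attr.name=\"weight\" attr.type=\"double\"/>",
    sprintf("  <graph id=\"%s\" edgedefault=\"directed\">", esc(p$view)))
  for (k in p$nodes) {
    lines <- c(lines,
               sprintf("    <node id=\"%s\">", esc(k)),
               sprintf("      <data key=\"d0\">%s</data>",
                       esc(unname(p$node_types[k]))),
               "    </node>")
  }
  e <- p$edges
  for (i in seq_len(nrow(e))) {
    body <- c(sprintf("      <data key=\"d1\">%s</data>", esc(e$predicate[i])),
              sprintf("      <data key=\"d2\">%d</data>", e$path_length[i]),
              sprintf("      <data key=\"d3\">%s</data>", esc(e$provenance[i])))
    if (!is.na(e$role[i])) {
      body <- c(body, sprintf("      <data key=\"d4\">%s</data>",
                              esc(e$role[i])))
    }
    if (!is.na(e$weight[i])) {
      body <- c(body, sprintf("      <data key=\"d5\">%s</data>",
                              format(e$weight[i], digits = 15)))
    }
    lines <- c(lines,
               sprintf("    <edge source=\"%s\" target=\"%s\">",
                       esc(e$subject[i]), esc(e$object[i])),
               body, "    </edge>")
  }
  paste(c(lines, "  </graph>", "</graphml>", ""), collapse = "\n")
}

.export_json <- function(p) {
  e <- p$edges
  obj <- list(
    view = p$view,
    directed = TRUE,
    nodes = lapply(p$nodes, function(k)
      list(id = k, node_type = unname(p$node_types[k]))),
    links = lapply(seq_len(nrow(e)), function(i) {
      l <- list(source = e$subject[i], target = e$object[i],
                predicate = e$predicate[i],
                path_length = e$path_length[i],
                provenance = e$provenance[i])
      if (!is.na(e$role[i])) l$role <- e$role[i]
      if (!is.na(e$weight[i])) l$weight <- e$weight[i]
      l
    }))
  paste0(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                          digits = NA), "\n")
}

.export_csv <- function(p) {
  e <- p$edges
  df <- data.frame(subject = e$subject, predicate = e$predicate,
                   object = e$object,
                   role = ifelse(is.na(e$role), "", e$role),
                   weight = ifelse(is.na(e$weight), "",
                                   format(e$weight, digits = 15)),
                   path_length = e$path_length,
                   provenance = e$provenance, stringsAsFactors = FALSE)
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Re-import an exported projection
#'
#' Reads GraphML or node-link JSON text produced by [export_projection()]
#' back into node and edge tables, for checking that exports preserve the
#' node and edge multisets.
#'
#' @param text Exported document text.
#' @param format `graphml` or `json`.
#' @return List with `nodes` (data frame: `id`, `node_type`) and `edges`
#'   (data frame: `subject`, `predicate`, `object`, `path_length`).
#' @export
import_projection <- function(text, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
    nodes <- do.call(rbind, lapply(obj$nodes, function(n)
      data.frame(id = n$id, node_type = n$node_type,
                 stringsAsFactors = FALSE)))
    edges <- do.call(rbind, lapply(obj$links, function(l)
      data.frame(subject = l$source, predicate = l$predicate,
                 object = l$target, path_length = l$path_length,
                 stringsAsFactors = FALSE)))
  } else {
    doc <- xml2::read_xml(text)
    ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
    nodes_x <- xml2::xml_find_all(doc, ".//g:node", ns)
    nodes <- data.frame(
      id = xml2::xml_attr(nodes_x, "id"),
      node_type = vapply(nodes_x, function(n)
        xml2::xml_text(xml2::xml_find_first(n, "./g:data[@key='d0']", ns)),
        ""),
      stringsAsFactors = FALSE)
    edges_x <- xml2::xml_find_all(doc, ".//g:edge", ns)
    edges <- data.frame(
      subject = xml2::xml_attr(edges_x, "source"),
      predicate = vapply(edges_x, function(n)
        xml2::xml_text(xml2::xml_find_first(n, "./g:data[@key='d1']", ns)),
        ""),
      object = xml2::xml_attr(edges_x, "target"),
      path_length = vapply(edges_x, function(n)
        as.integer(xml2::xml_text(
          xml2::xml_find_first(n, "./g:data[@key='d2']", ns))), 1L),
      stringsAsFactors = FALSE)
  }
  if (is.null(nodes)) nodes <- data.frame(id = character(),
                                          node_type = character())
  if (is.null(edges)) edges <- data.frame(subject = character(),
                                          predicate = character(),
                                          object = character(),
                                          path_length = integer())
  list(nodes = nodes, edges = edges)
}
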