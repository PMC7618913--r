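# Independent oracles used by the tests: these re-derive expected values
# by different algorithms (dynamic programming, union-find, plain BFS)
# than the package implementation uses.

# Needleman-Wunsch identity oracle: full DP with traceback under
# match +1 / mismatch -1 / gap -1, identity = matches / alignment length.
nw_identity_oracle <- function(a, b) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n)
  S[1, ] <- -(0:m)
  for (i in 1:n) {
    sub <- ifelse(A[i] == B, 1, -1)
    for (j in 1:m) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j], S[i, j + 1] - 1,
                             S[i + 1, j] - 1)
    }
  }
  i <- n; j <- m; matches <- 0L; alen <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (A[i] == B[j]) 1 else -1)) {
      matches <- matches + (A[i] == B[j])
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    alen <- alen + 1L
  }
  matches / alen
}

# Union-find component count over an undirected edge list.
union_find_components <- function(nodes, from, to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(from)) {
    ra <- find(from[i]); rb <- find(to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  length(unique(vapply(nodes, find, "")))
}

# Plain queue BFS distance on the undirected skeleton of a design graph.
bfs_distance_oracle <- function(g, from, to) {
  if (from == to) return(0L)
  adj <- list()
  for (i in seq_len(nrow(g$edges))) {
    s <- g$edges$subject[i]; o <- g$edges$object[i]
    adj[[s]] <- c(adj[[s]], o)
    adj[[o]] <- c(adj[[o]], s)
  }
  dist <- stats::setNames(0L, from)
  queue <- from
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (w in adj[[u]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[u] + 1L
        if (w == to) return(unname(dist[w]))
        queue <- c(queue, w)
      }
    }
  }
  NA_integer_
}

# Shared universe of small designs; random graphs are sampled as subsets
# of its roots (with their full subtrees), so any two samples agree on
# containment structure wherever they overlap.
design_universe <- function(n_roots = 8) {
  graphs <- lapply(seq_len(n_roots), function(i) {
    kind <- c("not_gate", "repressilator", "nested_design")[i %% 3 + 1]
    make_design(kind, seed = 1000L + i)$graph
  })
  graphs
}

sample_design_graph <- function(universe, p_keep = 0.6) {
  keep <- universe[stats::runif(length(universe)) < p_keep]
  if (!length(keep)) keep <- universe[1]
  combine(keep, "union")
}

# Bare projection over random nodes/edges, for component-count checks.
random_projection <- function(n_nodes, p_edge) {
  keys <- sprintf("https://rand.local/n%03d", seq_len(n_nodes))
  pairs <- utils::combn(keys, 2)
  sel <- which(stats::runif(ncol(pairs)) < p_edge)
  e <- data.frame(subject = pairs[1, sel], predicate = rep("represses",
                                                           length(sel)),
                  object = pairs[2, sel], role = rep(NA_character_,
                                                     length(sel)),
                  weight = rep(NA_real_, length(sel)),
                  provenance = paste(pairs[1, sel], pairs[2, sel],
                                     sep = "|"),
                  path_length = rep(1L, length(sel)),
                  stringsAsFactors = FALSE)
  structure(list(view = "interaction", nodes = keys,
                 node_types = stats::setNames(rep("Protein", n_nodes),
                                              keys),
                 edges = e, source = NULL),
            class = "projection_graph")
}

# Small SBOL2 document (read-only ingestion path).
sbol2_fixture_doc <- function() {
'<?xml version="1.0" encoding="UTF-8"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:sbol="http://sbols.org/v2#">
  <sbol:ComponentDefinition rdf:about="https://example.org/design2/root">
    <sbol:displayId>root</sbol:displayId>
    <sbol:component>
      <sbol:Component rdf:about="https://example.org/design2/root/c1">
        <sbol:definition rdf:resource="https://example.org/design2/pLac"/>
      </sbol:Component>
    </sbol:component>
    <sbol:component>
      <sbol:Component rdf:about="https://example.org/design2/root/c2">
        <sbol:definition rdf:resource="https://example.org/design2/lacI"/>
      </sbol:Component>
    </sbol:component>
  </sbol:ComponentDefinition>
  <sbol:ComponentDefinition rdf:about="https://example.org/design2/pLac">
    <sbol:displayId>pLac</sbol:displayId>
    <sbol:role rdf:resource="http://identifiers.org/so/SO:0000167"/>
  </sbol:ComponentDefinition>
  <sbol:ComponentDefinition rdf:about="https://example.org/design2/lacI">
    <sbol:displayId>lacI</sbol:displayId>
    <sbol:role rdf:resource="http://identifiers.org/so/SO:0000316"/>
    <sbol:sequence rdf:resource="https://example.org/design2/lacI_seq"/>
  </sbol:ComponentDefinition>
  <sbol:Sequence rdf:about="https://example.org/design2/lacI_seq">
    <sbol:elements>ATGGCAGCA</sbol:elements>
  </sbol:Sequence>
  <sbol:ComponentDefinition rdf:about="https://example.org/design2/LacI_protein">
    <sbol:displayId>LacI_protein</sbol:displayId>
    <sbol:type rdf:resource="http://www.biopax.org/release/biopax-level3.owl#Protein"/>
  </sbol:ComponentDefinition>
  <sbol:Interaction rdf:about="https://example.org/design2/repression1">
    <sbol:type rdf:resource="http://identifiers.org/biomodels.sbo/SBO:0000169"/>
    <sbol:participation>
      <sbol:Participation rdf:about="https://example.org/design2/repression1/p1">
        <sbol:role rdf:resource="http://identifiers.org/biomodels.sbo/SBO:0000020"/>
        <sbol:participant rdf:resource="https://example.org/design2/LacI_protein"/>
      </sbol:Participation>
    </sbol:participation>
    <sbol:participation>
      <sbol:Participation rdf:about="https://example.org/design2/repression1/p2">
        <sbol:role rdf:resource="http://identifiers.org/biomodels.sbo/SBO:0000642"/>
        <sbol:participant rdf:resource="https://example.org/design2/pLac"/>
      </sbol:Participation>
    </sbol:participation>
  </sbol:Interaction>
</rdf:RDF>'
}

# Tiny valid graph builders used across tests.
toy_graph <- function(nodes, edges = NULL) {
  g <- design_graph()
  for (i in seq_len(nrow(nodes))) {
    g <- graph_add_node(g, nodes$key[i], nodes$type[i])
  }
  for (i in seq_len(NROW(edges))) {
    g <- graph_add_edge(g, edges$subject[i], edges$predicate[i],
                        edges$object[i])
  }
  g
}

uri <- function(x) paste0("https://toy.local/", x)
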