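corpus_fixture <- function() {
  part_records(
    key = c("https://synbiohub.org/public/igem/BBa_R0010/1",
            "https://synbiohub.org/public/igem/BBa_C0012/1",
            "https://synbiohub.org/public/igem/BBa_B0010/1"),
    role = c("Promoter", "CDS", "Terminator"),
    name = c("BBa_R0010", "lacI", "BBa_B0010"),
    description = c("lac promoter", "lacI repressor CDS", "terminator"),
    sequence = c("TTGACAATTAATCATCGGCTCGTATAATGT",
                 "ATGGTGAATGTGAAACCAGTAACGTTATAC",
                 "CCAGGCATCAAATAAAACGAAAGGCTCAGT"),
    source = "igem_fixture")
}

test_that("node keys resolve against the corpus with ranked candidates", {
  r <- resolver(corpus_fixture(), "corpus_lookup")
  known <- validate_node_key("https://synbiohub.org/public/igem/BBa_R0010/1",
                             r)
  expect_true(known$valid)
  expect_equal(nrow(known$candidates), 0)

  bad <- validate_node_key("not a uri", r, name = "BBa_R0010")
  expect_false(bad$valid)
  expect_identical(bad$candidates$basis[1], "name")
  expect_identical(bad$candidates$key[1],
                   "https://synbiohub.org/public/igem/BBa_R0010/1")

  # an unknown key with a sequence identical to a corpus record ranks that
  # record first on sequence with score 1
  seqmatch <- validate_node_key(
    "https://example.org/unknown/part/1", r,
    sequence = "ATGGTGAATGTGAAACCAGTAACGTTATAC")
  expect_false(seqmatch$valid)
  expect_identical(seqmatch$candidates$key[1],
                   "https://synbiohub.org/public/igem/BBa_C0012/1")
  expect_identical(seqmatch$candidates$basis[1], "sequence")
  expect_equal(seqmatch$candidates$score[1], 1.0)

  # offline syntactic policy never consults the corpus
  off <- resolver(policy = "offline_syntactic")
  expect_true(validate_node_key("https://example.org/whatever", off)$valid)
  expect_false(validate_node_key("not a uri", off)$valid)
})

test_that("candidate ranking is deterministic for a fixed corpus", {
  r <- resolver(corpus_fixture(), "corpus_lookup", candidate_threshold = 0.1)
  c1 <- validate_node_key("not a uri", r, name = "BBa")$candidates
  c2 <- validate_node_key("not a uri", r, name = "BBa")$candidates
  expect_identical(c1, c2)
  expect_true(all(diff(c1$score) <= 0))
})

test_that("node additions enforce key validity, type vocabulary and identity", {
  g <- design_graph()
  r <- resolver(corpus_fixture(), "corpus_lookup")
  res <- add_node(g, "https://synbiohub.org/public/igem/BBa_R0010/1", "CDS",
                  c(name = "lacI", sequence = "ATGGCA"), r = r)
  expect_identical(res$request$status, "applied")
  n <- res$graph$nodes[["https://synbiohub.org/public/igem/BBa_R0010/1"]]
  expect_identical(n$type, "CDS")
  expect_identical(unname(n$properties["sequence"]), "ATGGCA")

  dup <- add_node(res$graph, "https://synbiohub.org/public/igem/BBa_R0010/1",
                  "CDS", r = r)
  expect_identical(dup$request$status, "rejected")
  expect_match(dup$request$reasons, "node exists")

  badtype <- add_node(g, "https://example.org/x", "Widget", force = TRUE)
  expect_identical(badtype$request$status, "rejected")
  expect_match(badtype$request$reasons, "unknown node type")

  unresolved <- add_node(g, "https://example.org/nowhere/1", "CDS", r = r)
  expect_identical(unresolved$request$status, "rejected")
  forced <- add_node(g, "https://example.org/nowhere/1", "CDS", r = r,
                     force = TRUE)
  expect_identical(forced$request$status, "applied")
})

test_that("typed predicate filtering accepts CDS->Protein production only", {
  g <- design_graph()
  g <- graph_add_node(g, uri("cds"), "CDS")
  g <- graph_add_node(g, uri("prot"), "Protein")
  g <- graph_add_node(g, uri("prom"), "Promoter")
  ok <- add_edge(g, "interaction", uri("cds"), "produces", uri("prot"))
  expect_identical(ok$request$status, "applied")
  p <- project(ok$graph, "interaction")
  hit <- p$edges[p$edges$predicate == "produces" &
                   p$edges$subject == uri("cds") &
                   p$edges$object == uri("prot"), ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$path_length, 2)

  badsub <- add_edge(g, "interaction", uri("prom"), "produces", uri("prot"))
  expect_identical(badsub$request$status, "rejected")
  expect_match(badsub$request$reasons[1], "subject type Promoter")
  badobj <- add_edge(g, "interaction", uri("cds"), "produces", uri("prom"))
  expect_identical(badobj$request$status, "rejected")
  unknown <- add_edge(g, "interaction", uri("ghost"), "produces", uri("prot"))
  expect_identical(unknown$request$status, "rejected")
  badview <- add_edge(g, "hierarchy", uri("cds"), "produces", uri("prot"))
  expect_identical(badview$request$status, "rejected")
})

test_that("interaction edits expand to one interaction node plus three triples", {
  g <- design_graph()
  g <- graph_add_node(g, uri("cds"), "CDS")
  g <- graph_add_node(g, uri("prot"), "Protein")
  before_nodes <- length(g$nodes)
  res <- add_edge(g, "interaction", uri("cds"), "produces", uri("prot"))
  added <- res$request$triples_added
  expect_equal(nrow(added), 3)
  expect_setequal(added$predicate,
                  c("interactionType", "hasParticipant"))
  expect_setequal(added$role[added$predicate == "hasParticipant"],
                  c("template", "product"))
  # one Interaction node plus the interaction-type term node
  types <- vapply(res$graph$nodes, `[[`, "", "type")
  expect_equal(sum(types == "Interaction"), 1)
  expect_equal(length(res$graph$nodes), before_nodes + 2)

  # minted keys use a deterministic counter
  ikey <- names(types)[types == "Interaction"]
  expect_match(ikey, "/interaction_1$")
  res2 <- add_edge(res$graph, "interaction", uri("cds"), "produces",
                   uri("prot"))
  types2 <- vapply(res2$graph$nodes, `[[`, "", "type")
  expect_true(any(grepl("/interaction_2$", names(types2))))
})

test_that("containment edits are applied directly and cycles are rejected", {
  g <- design_graph()
  g <- graph_add_node(g, uri("root"), "Engineered-Region")
  g <- graph_add_node(g, uri("unit"), "Engineered-Region")
  g <- graph_set_root(g, uri("root"))
  res <- add_edge(g, "hierarchy", uri("root"), "hasPart", uri("unit"))
  expect_identical(res$request$status, "applied")
  expect_equal(nrow(res$request$triples_added), 1)
  cyc <- add_edge(res$graph, "hierarchy", uri("unit"), "hasPart",
                  uri("root"))
  expect_identical(cyc$request$status, "rejected")
})

test_that("full-view edits add exactly the raw triple", {
  g <- design_graph()
  g <- graph_add_node(g, uri("cds"), "CDS")
  g <- graph_add_node(g, uri("prot"), "Protein")
  res <- add_edge(g, "full", uri("cds"), "produces", uri("prot"))
  expect_identical(res$request$status, "applied")
  expect_equal(nrow(res$request$triples_added), 1)
  expect_equal(length(res$graph$nodes), 2)
})

test_that("edit/projection commutation holds for every interaction predicate", {
  rules <- predicate_rules("interaction")
  for (rule in Filter(function(r) identical(r$expansion, "interaction"),
                      rules)) {
    g <- design_graph()
    g <- graph_add_node(g, uri("s"), rule$allowed_subject_types[1])
    g <- graph_add_node(g, uri("o"), rule$allowed_object_types[1])
    res <- add_edge(g, "interaction", uri("s"), rule$predicate, uri("o"))
    expect_identical(res$request$status, "applied")
    expect_length(validate_graph(res$graph), 0)
    p <- project(res$graph, "interaction")
    hit <- p$edges[p$edges$predicate == rule$predicate &
                     p$edges$subject == uri("s") &
                     p$edges$object == uri("o"), ]
    expect_equal(nrow(hit), 1, label = rule$predicate)
    expect_equal(hit$path_length, 2, label = rule$predicate)
    # verbose view shows the expanded participation pattern
    v <- project(res$graph, "interaction_verbose")
    expect_equal(nrow(v$edges), 2)
  }
})
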