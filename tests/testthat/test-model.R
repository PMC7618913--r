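test_that("node keys are normalized URIs with syntactic validation", {
  expect_true(is_absolute_uri("https://synbiohub.org/public/igem/BBa_R0010/1"))
  expect_true(is_absolute_uri("urn:example:abc"))
  expect_false(is_absolute_uri("not a uri"))
  expect_false(is_absolute_uri("no-scheme/path"))
  expect_identical(normalize_uri("https://x.org/a/"), "https://x.org/a")
  expect_identical(normalize_uri("https://x.org/a#frag"), "https://x.org/a")
  expect_identical(normalize_uri("https://x.org/a/1"), "https://x.org/a/1")
})

test_that("edge set has set semantics and canonical synonym direction", {
  g <- toy_graph(data.frame(key = uri(c("a", "b")),
                            type = c("CDS", "CDS")))
  g <- graph_add_edge(g, uri("a"), "similarTo", uri("b"), weight = 0.97)
  g <- graph_add_edge(g, uri("a"), "similarTo", uri("b"), weight = 0.97)
  expect_equal(nrow(g$edges), 1)
  g <- graph_add_edge(g, uri("b"), "synonymOf", uri("a"))
  syn <- g$edges[g$edges$predicate == "synonymOf", ]
  expect_equal(syn$subject, uri("a"))
  expect_equal(syn$object, uri("b"))
  # same triple with a different role qualifier is a distinct edge
  g2 <- toy_graph(data.frame(key = uri(c("i", "p")),
                             type = c("Interaction", "Protein")))
  g2 <- graph_add_edge(g2, uri("i"), "hasParticipant", uri("p"),
                       role = "inhibitor")
  g2 <- graph_add_edge(g2, uri("i"), "hasParticipant", uri("p"),
                       role = "product")
  expect_equal(nrow(g2$edges), 2)
})

test_that("validate_graph reports each broken invariant and passes fixtures", {
  expect_length(validate_graph(design_graph()), 0)

  g <- toy_graph(data.frame(key = uri("a"), type = "CDS"))
  g$edges <- rbind(g$edges, data.frame(
    subject = uri("a"), predicate = "hasPart", object = uri("missing"),
    role = NA_character_, weight = NA_real_))
  v <- validate_graph(g)
  expect_length(v, 1)
  expect_match(v, "dangling")

  expect_length(validate_graph(make_design("not_gate", seed = 11)$graph), 0)
  expect_length(validate_graph(make_design("repressilator", seed = 5)$graph),
                0)

  bad <- toy_graph(data.frame(key = uri("x"), type = "NotAType"))
  expect_match(validate_graph(bad), "not in vocabulary")
  badseq <- design_graph()
  badseq <- graph_add_node(badseq, uri("c"), "CDS",
                           c(sequence = "ATG!XQ"))
  expect_match(validate_graph(badseq), "IUPAC")
  badw <- toy_graph(data.frame(key = uri(c("a", "b")),
                               type = c("CDS", "CDS")))
  badw <- graph_add_edge(badw, uri("a"), "similarTo", uri("b"),
                         weight = 1.4)
  expect_match(validate_graph(badw), "weight")
})

test_that("containment restricted to root-reachable nodes must be a forest", {
  g <- design_graph()
  g <- graph_add_node(g, uri("root"), "Engineered-Region")
  g <- graph_add_node(g, uri("u1"), "Engineered-Region")
  g <- graph_add_node(g, uri("u2"), "Engineered-Region")
  g <- graph_set_root(g, uri("root"))
  g <- graph_add_edge(g, uri("root"), "hasPart", uri("u1"))
  g <- graph_add_edge(g, uri("u1"), "hasPart", uri("u2"))
  expect_length(validate_graph(g), 0)
  twoparents <- graph_add_edge(g, uri("root"), "hasPart", uri("u2"))
  expect_match(validate_graph(twoparents), "forest")
})

test_that("predicate rules depend on the view and encode the production rule", {
  ir <- predicate_rules("interaction")
  preds <- vapply(ir, `[[`, "", "predicate")
  expect_true(all(c("represses", "activates", "produces") %in% preds))
  hr <- predicate_rules("hierarchy")
  expect_identical(vapply(hr, `[[`, "", "predicate"), "hasPart")
  expect_error(predicate_rules("nonexistent_view"), "unregistered")

  prod <- Filter(function(r) r$predicate == "produces", ir)[[1]]
  expect_identical(prod$allowed_subject_types, "CDS")
  expect_identical(prod$allowed_object_types, "Protein")
})

test_that("the rule table round-trips through its JSON config format", {
  path <- withr::local_tempfile(fileext = ".json")
  default <- predicate_rules("interaction")
  jsonlite::write_json(
    lapply(default, function(r) r[c("predicate", "views",
                                    "allowed_subject_types",
                                    "allowed_object_types", "expansion")]),
    path, auto_unbox = FALSE)
  loaded <- load_rule_table(path)
  expect_identical(
    vapply(predicate_rules("interaction", rules = loaded), `[[`, "",
           "predicate"),
    vapply(default, `[[`, "", "predicate"))
})
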