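test_that("identical spec and seed give byte-identical fixtures", {
  for (kind in c("not_gate", "repressilator", "nested_design",
                 "genbank_flat")) {
    d1 <- make_design(kind, seed = 7)
    d2 <- make_design(kind, seed = 7)
    expect_identical(d1$doc, d2$doc, label = kind)
  }
  c1 <- make_part_corpus(seed = 9, n_records = 15, dup_rate = 0.2,
                         mutation_rate = 0.2)
  c2 <- make_part_corpus(seed = 9, n_records = 15, dup_rate = 0.2,
                         mutation_rate = 0.2)
  expect_identical(c1, c2)
  c3 <- make_part_corpus(seed = 10, n_records = 15, dup_rate = 0.2,
                         mutation_rate = 0.2)
  expect_false(identical(c1$records$sequence, c3$records$sequence))
  expect_error(make_design("flux_capacitor"), "invalid design kind")
})

test_that("fixture generation does not disturb the session RNG stream", {
  set.seed(555)
  before <- stats::runif(1)
  set.seed(555)
  invisible(make_design("repressilator", seed = 1))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("design manifests match the projected structure", {
  fx <- make_design("not_gate", seed = 2)
  p <- project(fx$graph, "interaction")
  expect_equal(nrow(p$edges), fx$manifest$interaction_view_edges)
  tab <- table(p$edges$predicate)
  expect_equal(as.integer(tab[names(fx$manifest$interaction_view_predicates)]),
               unname(fx$manifest$interaction_view_predicates))
  h <- project(fx$graph, "hierarchy")
  expect_equal(length(h$nodes), fx$manifest$hierarchy_nodes)
  expect_equal(nrow(h$edges), fx$manifest$hierarchy_edges)
  expect_length(g_viol <- validate_graph(fx$graph), 0)

  nest <- make_design("nested_design", seed = 4,
                      params = list(depth = 3, breadth = 2))
  hn <- project(nest$graph, "hierarchy")
  expect_equal(length(hn$nodes), nest$manifest$hierarchy_nodes)
  expect_equal(nrow(hn$edges), nest$manifest$hierarchy_edges)
})

test_that("planted corpus structure matches its manifest exactly", {
  corp <- make_part_corpus(seed = 7, n_records = 20, dup_rate = 0.1,
                           mutation_rate = 0)
  expect_equal(sum(corp$manifest$kind == "synonym"), 2)
  expect_equal(nrow(corp$records), 22)

  nomut <- make_part_corpus(seed = 8, n_records = 20, dup_rate = 0,
                            mutation_rate = 0)
  expect_equal(nrow(nomut$manifest), 0)

  # manifest identities are exactly reproduced by alignment
  mut <- make_part_corpus(seed = 12, n_records = 10, dup_rate = 0,
                          mutation_rate = 0.3, per_base_rate = 0.04)
  for (i in seq_len(nrow(mut$manifest))) {
    sa <- mut$records$sequence[mut$records$key == mut$manifest$a[i]]
    sb <- mut$records$sequence[mut$records$key == mut$manifest$b[i]]
    expect_equal(pairwise_identity(sa, sb), mut$manifest$identity[i],
                 tolerance = 1e-12)
  }

  # end to end: merge recovers every planted synonym pair
  corp2 <- make_part_corpus(seed = 21, n_records = 20, dup_rate = 0.2,
                            mutation_rate = 0)
  res <- merge_datasets(list(corp2$records), threshold = 0.95)
  planted <- corp2$manifest[corp2$manifest$kind == "synonym", ]
  expect_setequal(paste(res$report$synonyms$a, res$report$synonyms$b),
                  paste(planted$a, planted$b))
})

test_that("generated designs pass validation and io round trips", {
  for (seed in c(3, 8)) {
    fx <- make_design("repressilator", seed = seed)
    expect_length(validate_graph(fx$graph), 0)
    expect_true(graph_isomorphic(fx$graph, read_design(fx$doc)))
  }
})
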