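test_that("dataset filters remove duplicates first, then blank descriptions", {
  recs <- part_records(
    key = sprintf("https://src.local/p%d/1", 1:5),
    role = c("CDS", "CDS", "Promoter", "CDS", "Promoter"),
    name = sprintf("p%d", 1:5),
    description = c("a", "", "c", "", "e"),
    sequence = c("ATGAAA", "ATGAAA", "TTGACA", "ATGCCC", "TTGACA"),
    source = "src")
  both <- build_dataset(recs, c("drop_duplicates", "require_description"))
  # two exact (sequence, role) duplicates drop, then one blank description
  expect_equal(nrow(both$dataset), 2)
  expect_equal(sum(both$removed$reason == "duplicate"), 2)
  expect_equal(sum(both$removed$reason == "no_description"), 1)

  none <- build_dataset(recs)
  expect_equal(nrow(none$dataset), 5)
  alldesc <- build_dataset(
    part_records(key = sprintf("https://src.local/q%d/1", 1:3),
                 role = "CDS", name = "q", description = "",
                 sequence = c("AA", "CC", "GG")),
    "require_description")
  expect_equal(nrow(alldesc$dataset), 0)
})

test_that("alignment identity matches a dynamic-programming oracle", {
  a100 <- strrep("ACGT", 25)
  b100 <- a100
  substr(b100, 10, 10) <- "A"  # two isolated substitutions
  substr(b100, 50, 50) <- "G"
  expect_equal(pairwise_identity(a100, a100), 1.0)
  expect_equal(pairwise_identity(a100, b100), 0.98)
  expect_equal(pairwise_identity("A", "T"), 0.0)
  expect_error(pairwise_identity("", "ACGT"), "empty")

  # spaced substitutions keep the optimal alignment unique, so the oracle
  # and the implementation must agree exactly
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(40:120, 1)
    x <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    xs <- strsplit(x, "")[[1]]
    for (pos in seq(6, n - 6, by = 11)[seq_len(sample(1:4, 1))]) {
      xs[pos] <- sample(setdiff(c("A", "C", "G", "T"), xs[pos]), 1)
    }
    y <- paste(xs, collapse = "")
    expect_equal(pairwise_identity(x, y), nw_identity_oracle(x, y),
                 tolerance = 1e-12)
    expect_equal(pairwise_identity(x, y), pairwise_identity(y, x))
  }
})

test_that("identical records across sources become synonym nodes", {
  base <- make_part_corpus(seed = 5, n_records = 8, dup_rate = 0,
                           mutation_rate = 0)$records
  mirror <- base
  mirror$key <- sub("part", "mirror", mirror$key)
  mirror$name <- sub("part", "mirror", mirror$name)
  mirror$source <- "mirror_source"
  res <- merge_datasets(list(base, mirror), threshold = 0.95)
  expect_equal(nrow(res$report$synonyms), nrow(base))
  expect_equal(nrow(res$report$derivatives), 0)
  types <- vapply(res$graph$nodes, `[[`, "", "type")
  expect_equal(sum(types == "Synonym"), nrow(base))
  expect_equal(sum(res$graph$edges$predicate == "synonymOf"), nrow(base))
  expect_length(validate_graph(res$graph), 0)

  # merging k copies of one record leaves one part node and k-1 links
  tri <- base[1, ]
  copies <- list(base[1, , drop = FALSE])
  for (k in 2:3) {
    cp <- tri; cp$key <- sub("/1$", sprintf("_copy%d/1", k), cp$key)
    copies[[k]] <- cp
  }
  resk <- merge_datasets(copies, threshold = 0.95)
  typesk <- vapply(resk$graph$nodes, `[[`, "", "type")
  expect_equal(sum(typesk != "Synonym"), 1)
  expect_equal(nrow(resk$report$synonyms), 2)
})

test_that("planted derivatives are recovered exactly at the threshold", {
  corp <- make_part_corpus(seed = 17, n_records = 10, dup_rate = 0,
                           mutation_rate = 0.2, per_base_rate = 0.03)
  res <- merge_datasets(list(corp$records), threshold = 0.95)
  planted <- corp$manifest[corp$manifest$kind == "derivative" &
                             corp$manifest$identity >= 0.95, ]
  got <- res$report$derivatives
  expect_equal(nrow(got), nrow(planted))
  expect_setequal(paste(got$a, got$b),
                  paste(pmin(planted$a, planted$b),
                        pmax(planted$a, planted$b)))
  # reported identities equal the exact planted identities
  m <- match(paste(got$a, got$b),
             paste(pmin(planted$a, planted$b), pmax(planted$a, planted$b)))
  expect_equal(got$identity, planted$identity[m], tolerance = 1e-12)
  # similarTo edges carry the identity weight
  sim <- res$graph$edges[res$graph$edges$predicate == "similarTo", ]
  expect_equal(sort(sim$weight), sort(got$identity))
})

test_that("derivative detection is monotone in the threshold", {
  corp <- make_part_corpus(seed = 23, n_records = 15, dup_rate = 0,
                           mutation_rate = 0.3, per_base_rate = 0.05)
  lo <- merge_datasets(list(corp$records), threshold = 0.8)$report
  hi <- merge_datasets(list(corp$records), threshold = 0.95)$report
  expect_true(all(paste(hi$derivatives$a, hi$derivatives$b) %in%
                    paste(lo$derivatives$a, lo$derivatives$b)))
  expect_true(all(lo$derivatives$identity >= 0.8 &
                    lo$derivatives$identity < 1))
})

test_that("the k-mer prescreen changes no answers on fixture corpora", {
  corp <- make_part_corpus(seed = 29, n_records = 20, dup_rate = 0.1,
                           mutation_rate = 0.2, per_base_rate = 0.03)
  with_ps <- merge_datasets(list(corp$records), threshold = 0.95)
  no_ps <- merge_datasets(list(corp$records), threshold = 0.95,
                          use_prescreen = FALSE)
  expect_equal(with_ps$report$derivatives, no_ps$report$derivatives)
  expect_equal(with_ps$report$synonyms, no_ps$report$synonyms)
})

test_that("supplied interactions attach between surviving part nodes", {
  corp <- make_part_corpus(seed = 3, n_records = 6, dup_rate = 0.5,
                           mutation_rate = 0)
  syn <- corp$manifest[corp$manifest$kind == "synonym", ]
  # reference one survivor via its merged-away synonym key
  inter <- data.frame(subject = syn$b[1], predicate = "activates",
                      object = syn$a[2], stringsAsFactors = FALSE)
  res <- merge_datasets(list(corp$records), threshold = 0.95,
                        interactions = inter)
  act <- res$graph$edges[res$graph$edges$predicate == "activates", ]
  expect_equal(nrow(act), 1)
  expect_identical(act$subject, syn$a[1])  # remapped to the survivor
  expect_length(validate_graph(res$graph), 0)

  expect_error(merge_datasets(list(corp$records), threshold = 1.5),
               "threshold")
})

test_that("sources without shared sequence are disconnected components", {
  sets <- lapply(1:3, function(i)
    make_part_corpus(seed = 100 + i, n_records = 4, dup_rate = 0,
                     mutation_rate = 0,
                     source = sprintf("src%d", i))$records)
  res <- merge_datasets(sets, threshold = 0.95)
  ni <- network_info(project(res$graph, "full"))
  expect_equal(ni$component_count, 12)
  expect_equal(ni$edge_count, 0)
})
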