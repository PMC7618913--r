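test_that("the collapsed interaction view walks through interaction nodes", {
  fx <- make_design("not_gate", seed = 1)
  p <- project(fx$graph, "interaction")
  rep_e <- p$edges[p$edges$predicate == "represses", ]
  expect_equal(nrow(rep_e), 1)
  expect_identical(rep_e$subject, fx$manifest$repressor)
  expect_identical(rep_e$object, fx$manifest$repressed_promoter)
  expect_equal(rep_e$path_length, 2)
  expect_equal(nrow(p$edges), fx$manifest$interaction_view_edges)
  expect_equal(sum(p$edges$predicate == "produces"),
               unname(fx$manifest$interaction_view_predicates["produces"]))
})

test_that("interaction-view edge count is the sum over |active| x |passive|", {
  for (seed in c(1, 4)) {
    g <- make_design("repressilator", seed = seed)$graph
    types <- vapply(g$nodes, `[[`, "", "type")
    expected <- 0L
    for (ik in names(types)[types == "Interaction"]) {
      pp <- g$edges[g$edges$predicate == "hasParticipant" &
                      g$edges$subject == ik, ]
      n_act <- sum(pp$role %in% c("inhibitor", "stimulator", "template"))
      n_pas <- sum(pp$role %in% c("inhibited", "stimulated", "product"))
      expected <- expected + n_act * n_pas
    }
    p <- project(g, "interaction")
    expect_equal(nrow(p$edges), expected)
  }
})

test_that("the protein network contracts production into a regulatory cycle", {
  fx <- make_design("repressilator", seed = 2)
  p <- project(fx$graph, "protein_network")
  expect_setequal(p$nodes, fx$manifest$protein_cycle)
  expect_equal(nrow(p$edges), 3)
  expect_true(all(p$edges$predicate == "represses"))
  # each protein has out-degree 1 and in-degree 1: a directed 3-cycle
  expect_setequal(p$edges$subject, p$nodes)
  expect_setequal(p$edges$object, p$nodes)
  expect_false(any(p$edges$subject == p$edges$object))
})

test_that("hierarchy and verbose views restrict to their node families", {
  fx <- make_design("nested_design", seed = 1,
                    params = list(depth = 1, breadth = 4))
  h <- project(fx$graph, "hierarchy")
  expect_equal(length(h$nodes), fx$manifest$hierarchy_nodes)
  expect_equal(nrow(h$edges), fx$manifest$hierarchy_edges)
  expect_true(all(h$edges$subject == fx$graph$roots))  # depth-1 star
  expect_true(all(h$nodes %in% names(fx$graph$nodes)))

  g <- make_design("not_gate", seed = 1)$graph
  v <- project(g, "interaction_verbose")
  vtypes <- vapply(v$nodes, function(k) g$nodes[[k]]$type, "")
  expect_false("Metadata" %in% vtypes)
  expect_equal(sum(vtypes == "Interaction"), 2)
  expect_true(all(v$edges$predicate == "hasParticipant"))
  expect_false(any(is.na(v$edges$role)))
})

test_that("projections are deterministic and empty graphs project empty", {
  g <- make_design("repressilator", seed = 3)$graph
  for (view in c("full", "hierarchy", "interaction_verbose", "interaction",
                 "protein_network")) {
    p1 <- project(g, view)
    p2 <- project(g, view)
    expect_identical(export_projection(p1, "graphml"),
                     export_projection(p2, "graphml"))
    pe <- project(design_graph(), view)
    expect_length(pe$nodes, 0)
    expect_equal(nrow(pe$edges), 0)
  }
  expect_error(project(g, "bogus_view"), "unregistered")
})

test_that("network_info counts match the union-find oracle", {
  empty <- network_info(project(design_graph(), "full"))
  expect_equal(unlist(empty[c("node_count", "edge_count",
                              "component_count")]),
               c(node_count = 0, edge_count = 0, component_count = 0))

  two <- toy_graph(
    data.frame(key = uri(c("a", "b", "c", "d")), type = "Protein"),
    data.frame(subject = uri(c("a", "c")), predicate = "produces",
               object = uri(c("b", "d"))))
  ni <- network_info(project(two, "full"))
  expect_equal(ni$component_count, 2)

  set.seed(42)
  for (rep in 1:25) {
    p <- random_projection(n_nodes = sample(5:25, 1),
                           p_edge = stats::runif(1, 0.02, 0.2))
    ni <- network_info(p)
    expect_equal(ni$component_count,
                 union_find_components(p$nodes, p$edges$subject,
                                       p$edges$object))
    expect_equal(sum(as.integer(names(ni$degree_histogram)) *
                       ni$degree_histogram), 2 * ni$edge_count)
  }
})

test_that("shortest-path provenance is verified and corruption is caught", {
  g <- make_design("not_gate", seed = 1)$graph
  full <- project(g, "full")
  expect_true(all(full$edges$path_length == 1))
  inter <- project(g, "interaction")
  res <- shortest_path_annotation(inter)
  expect_length(res$mismatches, 0)
  # cross-check each recorded path length with an independent plain BFS
  for (i in seq_len(nrow(inter$edges))) {
    expect_equal(inter$edges$path_length[i],
                 bfs_distance_oracle(g, inter$edges$subject[i],
                                     inter$edges$object[i]))
  }
  corrupted <- inter
  corrupted$edges$path_length[1] <- 7L
  expect_match(shortest_path_annotation(corrupted)$mismatches, "7")
})
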