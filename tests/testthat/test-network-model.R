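test_that("bundled network loads with the curated structure", {
  g <- rp_network()
  expect_s3_class(g, "causal_graph")
  expect_equal(nrow(g$nodes), 28)
  expect_equal(g$outcome_id, "proliferation")
  expect_equal(sum(g$edges$feedback), 3)
  panel <- rp_gene_panel(g)
  expect_equal(nrow(panel), 25)
  expect_equal(length(unique(panel$node_id)), 15)
})

test_that("tiny networks load and invalid ones are rejected", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tlabel\tkind\tmeasurable\tgenes\tsufficient\texpected_direction",
               "A\tA node\tgene\tTRUE\tGenA\tTRUE\tup",
               "outcome\tOutcome\tprocess\tFALSE\t\tFALSE\tnone"),
             file.path(dir, "nodes.tsv"))
  writeLines(c("source\tsign\ttarget\tmechanism\trelationship_number\tfeedback",
               "A\tactivates\toutcome\tother\t1\tFALSE"),
             file.path(dir, "edges.tsv"))
  g <- load_network(dir)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$outcome_id, "outcome")

  # cycle among non-feedback edges
  writeLines(c("id\tlabel\tkind\tmeasurable\tgenes\tsufficient\texpected_direction",
               "A\tA\tprocess\tFALSE\t\tFALSE\tnone",
               "B\tB\tprocess\tFALSE\t\tFALSE\tnone",
               "outcome\tOutcome\tprocess\tFALSE\t\tFALSE\tnone"),
             file.path(dir, "nodes.tsv"))
  writeLines(c("source\tsign\ttarget\tmechanism\trelationship_number\tfeedback",
               "A\tactivates\tB\tother\t1\tFALSE",
               "B\tactivates\tA\tother\t2\tFALSE",
               "A\tactivates\toutcome\tother\t3\tFALSE"),
             file.path(dir, "edges.tsv"))
  expect_error(load_network(dir, outcome_id = "outcome"), "cycle")

  # dangling edge reference
  writeLines(c("source\tsign\ttarget\tmechanism\trelationship_number\tfeedback",
               "A\tactivates\tZZ\tother\t1\tFALSE",
               "A\tactivates\toutcome\tother\t2\tFALSE"),
             file.path(dir, "edges.tsv"))
  expect_error(load_network(dir, outcome_id = "outcome"), "missing node")
  expect_error(load_network(file.path(dir, "nope")), "not found")
})

test_that("graph invariants are enforced at construction", {
  nodes <- tibble::tibble(
    id = c("A", "out"), label = c("A", "out"),
    kind = c("gene", "process"), measurable = c(TRUE, FALSE),
    genes = list("GenA", character(0)),
    sufficient = c(TRUE, FALSE), expected_direction = c("up", "none"))
  edges <- tibble::tibble(source = "A", target = "out", sign = "activates",
                          mechanism = "other",
                          relationship_number = 1L, feedback = FALSE)
  expect_s3_class(causal_graph(nodes, edges, "out"), "causal_graph")

  bad <- nodes; bad$genes <- list(character(0), character(0))
  expect_error(causal_graph(bad, edges, "out"), "without mapped genes")
  bad <- nodes; bad$expected_direction <- c("none", "none")
  expect_error(causal_graph(bad, edges, "out"), "sufficient")
  expect_error(causal_graph(nodes, edges, "missing"), "outcome")
  bad_e <- rbind(edges, tibble::tibble(source = "out", target = "A",
                                       sign = "activates", mechanism = "other",
                                       relationship_number = 2L,
                                       feedback = FALSE))
  expect_error(causal_graph(nodes, bad_e, "out"), "outgoing")
})

test_that("working_dag strips feedback edges and is acyclic", {
  g <- rp_network()
  wd <- working_dag(g)
  expect_equal(nrow(wd$nodes), nrow(g$nodes))
  expect_equal(nrow(wd$edges), nrow(g$edges) - 3)
  expect_false(any(wd$edges$feedback))
  expect_true(igraph::is_dag(as_igraph(wd)))
  # graph with no feedback edges is unchanged
  expect_identical(working_dag(wd)$edges, wd$edges)
  # chain with a flagged back-edge reduces to the chain
  chain <- toy_graph(rbind(c("A", "B"), c("B", "C")), c("A", "B", "C"))
  chain$edges <- rbind(chain$edges,
                       tibble::tibble(source = "C", target = "A",
                                      sign = "activates", mechanism = "other",
                                      relationship_number = NA_integer_,
                                      feedback = TRUE))
  expect_equal(nrow(working_dag(chain)$edges), 2)
})

test_that("node parents follow the working DAG", {
  g <- rp_network()
  expect_true("g1s_dysregulation" %in% node_parents(g, "proliferation"))
  expect_equal(node_parents(g, "oxidative_stress"), character(0))
  # feedback edge does not make tcf_lef a parent of axin's target set
  expect_equal(node_parents(g, "axin"), "dvl1")
  expect_equal(node_parents(g, "rb1"), c("cyclin_cdk", "psmd10"))
  chain <- toy_graph(rbind(c("A", "B")), c("A", "B"))
  expect_equal(node_parents(chain, "B"), "A")
  expect_error(node_parents(g, "nope"), "unknown")
})

test_that("d-separation handles chains, forks and colliders", {
  chain <- toy_graph(rbind(c("A", "B"), c("B", "C")), c("A", "B", "C"))
  expect_true(d_separated(chain, "A", "C", "B"))
  expect_false(d_separated(chain, "A", "C"))
  fork <- toy_graph(rbind(c("B", "A"), c("B", "C")), c("A", "B", "C"))
  expect_true(d_separated(fork, "A", "C", "B"))
  expect_false(d_separated(fork, "A", "C"))
  coll <- toy_graph(rbind(c("A", "C"), c("B", "C")), c("A", "B", "C"))
  expect_true(d_separated(coll, "A", "B"))
  expect_false(d_separated(coll, "A", "B", "C"))
  colld <- toy_graph(rbind(c("A", "C"), c("B", "C"), c("C", "D")),
                     c("A", "B", "C", "D"))
  expect_false(d_separated(colld, "A", "B", "D"))
  expect_error(d_separated(chain, "A", "Z"), "unknown")
  expect_error(d_separated(chain, "A", "C", c("B", "A")), "conditioning")
})

test_that("d-separation is symmetric and matches the oracle on random DAGs", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    ed <- random_dag(n)
    res <- check_dsep_against_oracle(ed, n)
    expect_true(res$ok, info = paste("disagreement:", paste(
      utils::capture.output(str(res)), collapse = " ")))
    nodes <- paste0("n", seq_len(n))
    g <- toy_graph(if (nrow(ed)) cbind(nodes[ed[, 1]], nodes[ed[, 2]])
                   else NULL, nodes)
    pair <- sample(n, 2)
    S <- nodes[setdiff(sample(n, sample(0:(n - 2), 1)), pair)]
    expect_identical(d_separated(g, nodes[pair[1]], nodes[pair[2]], S),
                     d_separated(g, nodes[pair[2]], nodes[pair[1]], S))
  }
})

test_that("observing every chain node keeps separated pairs separated", {
  # conditioning on a full chain between a and b blocks it; only collider
  # descendants can re-open dependence
  chain4 <- toy_graph(rbind(c("A", "B"), c("B", "C"), c("C", "D")),
                      c("A", "B", "C", "D"))
  expect_true(d_separated(chain4, "A", "D", c("B", "C")))
  expect_true(d_separated(chain4, "A", "D", "B"))
  mixed <- toy_graph(rbind(c("A", "B"), c("C", "B"), c("C", "D")),
                     c("A", "B", "C", "D"))
  expect_true(d_separated(mixed, "A", "D"))       # blocked at collider B
  expect_false(d_separated(mixed, "A", "D", "B")) # opened by observing it
})

test_that("local Markov property holds on the fixture", {
  g <- rp_network()
  expect_true(locally_markov_independent(g, "rb1", "myc"))
  for (p in node_parents(g, "rb1")) {
    expect_false(locally_markov_independent(g, "rb1", p))
  }
  chain <- toy_graph(rbind(c("A", "B"), c("B", "C")), c("A", "B", "C"))
  expect_true(locally_markov_independent(chain, "C", "A"))
  expect_error(locally_markov_independent(chain, "A", "C"),
               "non-descendant")
})

test_that("sufficient events combine proximity and curation with an audit", {
  g <- rp_network()
  se <- sufficient_events(g)
  expect_setequal(se$sufficient, c("ccnd1", "rb1", "cdk4_6", "psmd10"))
  expect_setequal(se$proteins, c("Ccnd1", "Rb1", "Cdk4", "Cdk6", "Psmd10"))
  expect_length(se$proteins, 5)
  expect_equal(se$flagged_not_proximal, character(0))
  expect_true("foxm1" %in% se$proximal_not_flagged)
  expect_length(sufficient_events(g, max_depth = 0)$sufficient, 0)

  mini_nodes <- tibble::tibble(
    id = c("A", "out"), label = c("A", "out"),
    kind = c("gene", "process"), measurable = c(TRUE, FALSE),
    genes = list("GenA", character(0)),
    sufficient = c(TRUE, FALSE), expected_direction = c("up", "none"))
  mini_edges <- tibble::tibble(source = "A", target = "out",
                               sign = "activates", mechanism = "other",
                               relationship_number = NA_integer_,
                               feedback = FALSE)
  mini <- causal_graph(mini_nodes, mini_edges, "out")
  expect_equal(sufficient_events(mini)$sufficient, "A")
})

test_that("network round-trips through the writers", {
  g <- rp_network()
  dir <- withr::local_tempdir()
  write_network(g, file.path(dir, "net"))
  g2 <- load_network(file.path(dir, "net"), outcome_id = "proliferation")
  expect_equal(g2$nodes$id, g$nodes$id)
  expect_equal(g2$nodes$genes, g$nodes$genes)
  expect_equal(g2$edges, g$edges)

  sif <- file.path(dir, "net.sif")
  export_sif(g, sif)
  lines <- strsplit(readLines(sif), "\t")
  expect_equal(length(lines), nrow(g$edges))
  expect_true(all(vapply(lines, length, 1L) == 3))
  expect_true(all(vapply(lines, `[`, "", 2) %in% c("activates", "inhibits")))

  gml <- file.path(dir, "net.graphml")
  export_graphml(g, gml)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(ig), 28)
  expect_equal(igraph::ecount(ig), nrow(g$edges))
})
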