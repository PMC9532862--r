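fake_edges <- function() {
  cm <- tibble::tibble(mirna = c("m1", "m2"), target = c("c1", "c1"),
                       kind = "circRNA-miRNA",
                       coefficient = c(-0.9, -0.8), method = "spearman",
                       n_samples = 6L, passed = TRUE)
  mg <- tibble::tibble(mirna = c("m1", "m2"), target = c("g1", "g2"),
                       kind = "miRNA-mRNA",
                       coefficient = c(-0.95, -0.75), method = "spearman",
                       n_samples = 6L, passed = TRUE)
  cg <- tibble::tibble(circ = c("c1", "c1"), mrna = c("g1", "g2"),
                       kind = "circRNA-mRNA",
                       coefficient = c(0.97, 0.93), method = "pearson",
                       n_samples = 6L, passed = c(TRUE, TRUE))
  sp <- tibble::tibble(circ = c("c1", "c1"), mrna = c("g1", "g2"),
                       k = c(2L, 1L), p = c(0.001, 0.03),
                       passed = c(TRUE, TRUE))
  list(cm = cm, mg = mg, cg = cg, sp = sp)
}

test_that("triples require all four supporting conditions", {
  e <- fake_edges()
  tr <- assemble_triples(e$cm, e$mg, e$cg, e$sp)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$circ, c("c1", "c1"))
  expect_equal(tr$mirna, c("m1", "m2"))
  expect_equal(tr$mrna, c("g1", "g2"))

  # no circRNA-miRNA edges -> nothing
  none <- assemble_triples(e$cm[0, ], e$mg, e$cg, e$sp)
  expect_equal(nrow(none), 0)
  # failing the sponge test removes the triple
  sp2 <- e$sp; sp2$passed[1] <- FALSE
  expect_equal(nrow(assemble_triples(e$cm, e$mg, e$cg, sp2)), 1)
  # duplicated input rows do not duplicate triples
  dup <- assemble_triples(e$cm[c(1, 1, 2), ], e$mg, e$cg, e$sp)
  expect_equal(nrow(dup), 2)
})

test_that("network counts, degrees and the summary line are exact", {
  e <- fake_edges()
  tr <- assemble_triples(e$cm, e$mg, e$cg, e$sp)
  net <- build_network(tr)
  expect_equal(sort(net$nodes$id), c("c1", "g1", "g2", "m1", "m2"))
  expect_equal(nrow(net$edges), 4)
  expect_equal(network_summary(net),
               "1 circRNA nodes, 2 miRNA nodes, 2 mRNA nodes, and 4 edges")
  expect_equal(sum(table(net$nodes$type)), nrow(net$nodes))
  # independent recount from the triple table
  expect_equal(nrow(net$nodes),
               length(unique(c(tr$circ, tr$mirna, tr$mrna))))
  # single triple: 3 nodes, 2 edges
  one <- build_network(tr[1, ])
  expect_equal(nrow(one$nodes), 3)
  expect_equal(nrow(one$edges), 2)
  # optional circRNA-mRNA support edges
  with_cg <- build_network(tr, include_circ_mrna = TRUE)
  expect_equal(nrow(with_cg$edges), 6)
})

test_that("hub ranking is by degree with lexicographic ties", {
  e <- fake_edges()
  net <- build_network(assemble_triples(e$cm, e$mg, e$cg, e$sp))
  hubs <- hub_rank(net)
  # c1, m1, m2 all have degree 2; lexicographic tie-break puts c1 first
  expect_equal(hubs$id, c("c1", "m1", "m2", "g1", "g2"))
  expect_equal(hubs$degree, c(2, 2, 2, 1, 1))
})

test_that("top-k keeps the best edges by sponge p then |coefficient|", {
  e <- fake_edges()
  net <- build_network(assemble_triples(e$cm, e$mg, e$cg, e$sp))
  expect_equal(nrow(top_edges(net, k = 100)$edges), nrow(net$edges))
  best <- top_edges(net, k = 1)
  expect_equal(nrow(best$edges), 1)
  # lowest sponge p (0.001) then strongest |coefficient| (-0.95 mir-mRNA)
  expect_equal(best$edges$sponge_p, 0.001)
  expect_equal(best$edges$coefficient, -0.95)
  expect_equal(nrow(top_edges(net, k = 3)$edges), 3)
  expect_error(top_edges(net, k = 0), ">= 1")
})

test_that("exports write Cytoscape-readable text", {
  e <- fake_edges()
  net <- build_network(assemble_triples(e$cm, e$mg, e$cg, e$sp))
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, sif)
  lines <- readLines(sif)
  expect_equal(length(lines), 4)
  expect_true(all(lengths(strsplit(lines, "\t")) == 3))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), 5)
  expect_equal(igraph::ecount(g2), 4)
})
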