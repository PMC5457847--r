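demo_triples <- function() {
  demirs <- tibble::tibble(feature = c("m1", "m2"), direction = c("up", "up"))
  degs <- tibble::tibble(feature = c("g1", "g2", "g3"),
                         direction = c("down", "up", "down"))
  pathways <- gene_set_collection(list(P1 = c("g1", "g2", "g9"),
                                       P2 = c("g3", "g4")))
  targets <- target_map(c("m1", "m1", "m2", "m2"),
                        c("g1", "g2", "g3", "g9"))
  risk <- identify_risk_genes(c("g1", "g2", "g3"), degs, pathways,
                              c("P1", "P2"))
  build_triples(demirs, risk, c("P1", "P2"), targets, pathways)
}

test_that("risk genes are the exact core/DEG intersection with annotations", {
  degs <- tibble::tibble(feature = c("b", "c", "d"),
                         direction = c("up", "down", "up"))
  rg <- identify_risk_genes(c("a", "b", "c"), degs)
  expect_equal(rg$gene, c("b", "c"))
  expect_equal(rg$direction, c("up", "down"))

  expect_warning(empty <- identify_risk_genes(c("a"), degs["d" == degs$feature, ]),
                 "disjoint")
  expect_equal(nrow(empty), 0)

  pw <- gene_set_collection(list(P1 = c("b", "z"), P2 = c("c")))
  rg2 <- identify_risk_genes(c("b", "c"), degs, pw, c("P1", "P2"))
  expect_equal(rg2$pathways[[1]], "P1")
  expect_equal(rg2$pathways[[2]], "P2")
})

test_that("triples require target, membership, risk pathway and carry concordance", {
  tr <- demo_triples()
  expect_setequal(paste(tr$mirna, tr$gene, tr$pathway),
                  c("m1 g1 P1", "m1 g2 P1", "m2 g3 P2"))
  expect_equal(tr$concordance[tr$gene == "g1"], "opposite")
  expect_equal(tr$concordance[tr$gene == "g2"], "same")
  expect_equal(tr$concordance[tr$gene == "g3"], "opposite")
})

test_that("network keeps PPI edges only between risk genes in triples", {
  tr <- demo_triples()
  ppi <- ppi_network(c("g1", "g1", "g2"), c("g2", "g7", "g3"))
  net <- build_network(tr, ppi)
  expect_setequal(net$nodes$id[net$nodes$type == "gene"],
                  c("g1", "g2", "g3"))
  ppi_edges <- net$edges[net$edges$type == "ppi", ]
  key <- paste(pmin(ppi_edges$from, ppi_edges$to),
               pmax(ppi_edges$from, ppi_edges$to))
  expect_setequal(key, c("g1 g2", "g2 g3"))  # g7 is not a risk gene
  # degree sum identity
  g <- as_igraph(net)
  expect_equal(sum(igraph::degree(g)), 2 * nrow(net$edges))

  single <- demo_triples()[1, ]
  net1 <- build_network(single, ppi_network("g1", "h9"))
  expect_equal(nrow(net1$edges), 2)
  expect_setequal(net1$edges$type, c("targets", "member_of"))
})

test_that("hand-computed topology of the triangle and the path graph", {
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("a", "b", "c")
  topo <- node_topology(k3)
  expect_equal(topo$clustering, rep(1, 3))
  expect_equal(topo$topological_coefficient, rep(1, 3))
  expect_equal(topo$betweenness, rep(0, 3))
  expect_equal(topo$closeness, rep(1, 3))
  expect_equal(topo$avg_shortest_path, rep(1, 3))

  path <- igraph::make_graph(~ A - B, B - C)
  tp <- node_topology(path)
  expect_equal(tp$betweenness[tp$node == "B"], 1)
  expect_equal(tp$closeness[tp$node == "B"], 1)
  expect_equal(tp$closeness[tp$node == "A"], 2 / 3)
  expect_equal(tp$avg_shortest_path[tp$node == "A"], 1.5)
  expect_equal(tp$clustering, rep(0, 3))
})

test_that("all six metrics agree with the brute-force oracle on random graphs", {
  for (s in 1:25) {
    n <- sample(5:30, 1)
    g <- random_simple_graph(n, p = 0.18, seed = s)
    topo <- node_topology(g)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    oracle <- oracle_topology(A)
    o <- match(topo$node, rownames(A))
    expect_equal(topo$degree, unname(oracle$degree[o]))
    expect_equal(topo$betweenness, unname(oracle$betweenness[o]),
                 tolerance = 1e-9)
    expect_equal(topo$closeness, unname(oracle$closeness[o]),
                 tolerance = 1e-9)
    expect_equal(topo$clustering, unname(oracle$clustering[o]),
                 tolerance = 1e-9)
    expect_equal(topo$avg_shortest_path, unname(oracle$avg_shortest_path[o]),
                 tolerance = 1e-9)
    expect_equal(topo$topological_coefficient,
                 unname(oracle$topological_coefficient[o]), tolerance = 1e-9)
  }
})

test_that("hub ranking is by degree with betweenness then id tie-breaks", {
  topo <- tibble::tibble(
    node = c("a", "b", "c", "d"),
    degree = c(3L, 3L, 3L, 1L),
    betweenness = c(2, 5, 2, 0)
  )
  hubs <- top_hubs(topo, 3)
  expect_equal(hubs$node, c("b", "a", "c"))
})

test_that("concordance counts deduplicate miRNA-gene pairs across pathways", {
  tr <- tibble::tibble(
    mirna = c("m", "m", "m"), gene = c("g", "g", "h"),
    pathway = c("P1", "P2", "P1"),
    mirna_direction = "up", gene_direction = c("down", "down", "up"),
    concordance = c("opposite", "opposite", "same")
  )
  cc <- classify_concordance(tr)
  expect_equal(cc$opposite, 1)
  expect_equal(cc$same, 1)
  expect_equal(nrow(cc$pairs), 2)

  empty <- classify_concordance(tr[0, ])
  expect_equal(c(empty$opposite, empty$same), c(0, 0))
})

test_that("empty graphs yield an empty topology table", {
  expect_equal(nrow(node_topology(igraph::make_empty_graph(0))), 0)
})
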