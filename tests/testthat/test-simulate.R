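test_that("expression simulation is deterministic and plants exact shifts", {
  a <- make_study(seed = 5)
  b <- make_study(seed = 5)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, make_study(seed = 6)$values))

  st <- make_study(n_features = 3, n_case = 9, n_control = 9,
                   effects = c(G001 = 10), noise_sd = 0.1, seed = 2)
  diff <- mean(st$values["G001", st$labels == "case"]) -
    mean(st$values["G001", st$labels == "control"])
  expect_lt(abs(diff - 10), 0.2)
})

test_that("null simulation rejects at the nominal 5% rate", {
  st <- make_study(n_features = 1000, n_case = 9, n_control = 9, seed = 9)
  tab <- welch_t_table(st)
  rate <- mean(tab$p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("preferential attachment gives a connected scale-free graph", {
  tree <- simulate_scale_free_ppi(5, attachment = 1, seed = 1)
  expect_equal(nrow(tree), 4)

  expect_identical(simulate_scale_free_ppi(50, 2, seed = 3),
                   simulate_scale_free_ppi(50, 2, seed = 3))
  expect_error(simulate_scale_free_ppi(3, 5), "n_nodes > attachment")

  heavy <- vapply(1:100, function(s) {
    net <- simulate_scale_free_ppi(200, 2, seed = s)
    g <- igraph::graph_from_data_frame(net, directed = FALSE)
    deg <- igraph::degree(g)
    max(deg) >= 4 * stats::median(deg)
  }, logical(1))
  expect_gte(mean(heavy), 0.95)
})

test_that("bundle truth record is internally consistent", {
  b <- simulate_bundle(small_bundle_config(seed = 7))
  tr <- b$truth
  pair_key <- paste(b$targets$mirna, b$targets$gene)
  expect_true(all(paste(tr$triples$mirna, tr$triples$gene) %in% pair_key))
  expect_true(all(mapply(function(g, p) g %in% b$pathways[[p]],
                         tr$triples$gene, tr$triples$pathway)))
  expect_true(all(tr$triples$gene %in% tr$de_genes$gene))
  expect_true(all(tr$triples$mirna %in% tr$de_mirnas$mirna))
  # planted miRNA targets over-populate the planted pathway (>= 5x density)
  for (i in seq_len(nrow(tr$risk_pairs))) {
    m <- tr$risk_pairs$mirna[i]; pw <- tr$risk_pairs$pathway[i]
    tg <- b$targets$gene[b$targets$mirna == m]
    inside <- length(intersect(tg, b$pathways[[pw]])) / length(b$pathways[[pw]])
    background <- length(tg) / b$config$n_genes
    expect_gte(inside, 5 * background)
  }
})

test_that("planted risk-pair count and DE-free configurations are honored", {
  cfg1 <- simulation_config(n_genes = 300, n_mirnas = 30, n_pathways = 4,
                            pathway_size = c(8, 12), targets_per_mirna = 8,
                            n_planted_risk_pairs = 1, n_shared_de = 1,
                            seed = 3)
  b1 <- simulate_bundle(cfg1)
  expect_equal(nrow(b1$truth$risk_pairs), 1)

  # no planted effects at all: truth lists only the unavoidable planted
  # pathway genes unless the fraction is forced to zero by configuration
  cfg0 <- simulation_config(n_genes = 2100, n_mirnas = 30, n_pathways = 4,
                            pathway_size = c(8, 12), targets_per_mirna = 8,
                            fraction_de_genes = 1e-9, effect_size = 1e-9,
                            n_planted_risk_pairs = 1, n_shared_de = 1,
                            seed = 3)
  b0 <- simulate_bundle(cfg0)
  tab <- welch_t_table(b0$mrna_studies[[1]])
  rate <- mean(tab$p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("bundles serialize to the standard formats and re-load", {
  b <- simulate_bundle(small_bundle_config(seed = 4))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  st <- read_expression_matrix(file.path(dir, "mrna_1.tsv"),
                               b$mrna_studies[[1]]$labels)
  expect_equal(st$values, b$mrna_studies[[1]]$values, tolerance = 1e-12)
  gs <- read_gmt(file.path(dir, "pathways.gmt"))
  expect_identical(names(gs), names(b$pathways))
  expect_equal(as.list(gs), as.list(b$pathways), ignore_attr = TRUE)
  tm <- read_interaction_table(file.path(dir, "targets.tsv"))
  expect_setequal(paste(tm$mirna, tm$gene),
                  paste(b$targets$mirna, b$targets$gene))
  ppi <- read_edge_list(file.path(dir, "ppi.tsv"))
  expect_equal(nrow(ppi), nrow(b$ppi))
})
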