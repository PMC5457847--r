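ranked_tbl <- function(features, metric) {
  tibble::tibble(feature = features, metric = metric)
}

test_that("signal-to-noise ranking matches the hand formula with sd floors", {
  # case mean 2 sd 0.5, control mean 1 sd 0.5 -> metric 1.0
  vals <- rbind(A = c(1.5, 2, 2.5, 0.5, 1, 1.5),
                B = c(0.5, 1, 1.5, 1.5, 2, 2.5),
                C = c(1, 2, 3, 1, 2, 3))
  colnames(vals) <- sprintf("s%d", 1:6)
  st <- study_from_matrix(vals, n_case = 3)
  rk <- rank_by_signal_to_noise(st)
  expect_equal(rk$metric[rk$feature == "A"], 1.0, tolerance = 1e-12)
  expect_equal(rk$metric[rk$feature == "B"], -1.0, tolerance = 1e-12)
  expect_equal(rk$metric[rk$feature == "C"], 0)
  expect_equal(rk$feature, c("A", "C", "B"))  # zero metric between +/-

  # sd floor: tiny group sd is lifted to max(0.2|mu|, 0.2)
  vals2 <- rbind(D = c(10, 10.0001, 10.0002, 0, 0.0001, 0.0002))
  colnames(vals2) <- sprintf("s%d", 1:6)
  st2 <- study_from_matrix(vals2, n_case = 3)
  rk2 <- rank_by_signal_to_noise(st2)
  mu1 <- mean(vals2[1, 1:3]); mu2 <- mean(vals2[1, 4:6])
  expect_equal(rk2$metric,
               (mu1 - mu2) / (0.2 * abs(mu1) + 0.2), tolerance = 1e-9)

  expect_error(rank_by_signal_to_noise(make_study(n_case = 2, n_control = 5)),
               ">=3 samples")
})

test_that("metric ties are broken lexicographically and stably", {
  vals <- matrix(rep(c(2, 2, 2, 1, 1, 1), each = 3), nrow = 3, byrow = FALSE)
  rownames(vals) <- c("Z", "A", "M")
  colnames(vals) <- sprintf("s%d", 1:6)
  st <- study_from_matrix(vals, n_case = 3)
  expect_equal(rank_by_signal_to_noise(st)$feature, c("A", "M", "Z"))
})

test_that("enrichment score reproduces hand-walked cases", {
  # all hits before all misses, equal metrics -> ES = 1
  r <- ranked_tbl(paste0("g", 1:10), c(2, 2, rep(1, 8)))
  es <- enrichment_score(r, c("g1", "g2"), weight = 1)
  expect_equal(es$es, 1.0)
  expect_setequal(es$leading_edge, c("g1", "g2"))

  # mirror case: set at the bottom -> ES = -1
  es2 <- enrichment_score(r, c("g9", "g10"), weight = 1)
  expect_equal(es2$es, -1.0)
  expect_setequal(es2$leading_edge, c("g9", "g10"))

  # weight 0, list g1..g4, set {g1, g3}: walk (0.5, 0, 0.5, 0), ES 0.5
  r4 <- ranked_tbl(paste0("g", 1:4), c(4, 3, 2, 1))
  es3 <- enrichment_score(r4, c("g1", "g3"), weight = 0)
  expect_equal(es3$walk, c(0.5, 0, 0.5, 0))
  expect_equal(es3$es, 0.5)

  # empty intersection is skipped with a warning, no result
  expect_warning(out <- enrichment_score(r4, "absent"), "skip")
  expect_null(out)
})

test_that("walk returns to zero and ES stays in [-1, 1] on random inputs", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    metric <- sort(rnorm(n), decreasing = TRUE)
    m <- sample(1:(n - 1), 1)
    hit_set <- paste0("g", sample(n, m))
    es <- enrichment_score(ranked_tbl(paste0("g", 1:n), metric), hit_set,
                           weight = sample(c(0, 1, 1.5), 1))
    expect_lt(abs(es$walk[n]), 1e-9)
    expect_gte(es$es, -1)
    expect_lte(es$es, 1)
  }
})

test_that("weight-0 enrichment equals the brute-force KS walk on short lists", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    metric <- sort(rnorm(n), decreasing = TRUE)
    m <- sample(1:(n - 1), 1)
    hits <- seq_len(n) %in% sample(n, m)
    es <- enrichment_score(ranked_tbl(paste0("g", 1:n), metric),
                           paste0("g", which(hits)), weight = 0)
    oracle <- oracle_walk(metric, hits, weight = 0)
    expect_equal(es$walk, oracle$walk, tolerance = 1e-12)
    expect_equal(es$es, oracle$es, tolerance = 1e-12)
  }
})

test_that("reversing the ranked list negates the weight-0 score", {
  set.seed(11)
  for (i in 1:50) {
    n <- 15
    metric <- sort(rnorm(n), decreasing = TRUE)
    hits <- paste0("g", sample(n, 4))
    fwd <- enrichment_score(ranked_tbl(paste0("g", 1:n), metric),
                            hits, weight = 0)
    rev_ <- enrichment_score(ranked_tbl(paste0("g", n:1), rev(metric)),
                             hits, weight = 0)
    expect_equal(abs(fwd$es), abs(rev_$es), tolerance = 1e-12)
    # the signed identity holds whenever the two extrema are not tied
    if (abs(max(fwd$walk) + min(fwd$walk)) > 1e-9) {
      expect_equal(fwd$es, -rev_$es, tolerance = 1e-12)
    }
  }
})

test_that("weighted scores agree with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(19)
  for (i in 1:50) {
    n <- sample(20:100, 1)
    metric <- sort(rnorm(n), decreasing = TRUE)
    m <- sample(2:10, 1)
    idx <- sort(sample(n, m))
    es <- enrichment_score(ranked_tbl(paste0("g", 1:n), metric),
                           paste0("g", idx), weight = 1)
    ref <- fgsea::calcGseaStat(metric, selectedStats = idx, gseaParam = 1)
    expect_equal(es$es, ref, tolerance = 1e-9)
  }
})

test_that("permutation p is deterministic and detects a planted pathway", {
  st <- make_study(n_features = 300, n_case = 9, n_control = 9,
                   effects = setNames(rep(1, 20), sprintf("G%03d", 1:20)),
                   noise_sd = 0.5, seed = 23)
  pw <- sprintf("G%03d", 1:20)
  p1 <- gsea_permutation_p(st, pw, n_perm = 100, seed = 5)
  p2 <- gsea_permutation_p(st, pw, n_perm = 100, seed = 5)
  expect_identical(p1, p2)
  expect_lte(p1, 0.02)
  expect_gte(p1, 1 / 101)
})

test_that("few distinct label permutations triggers the replacement notice", {
  st <- make_study(n_features = 30, n_case = 2, n_control = 2, seed = 3)
  expect_message(
    gsea_scan(st, list(s = sprintf("G%03d", 1:5)), n_perm = 10, seed = 1),
    "with replacement"
  )
})

test_that("risk-pathway selection applies the strict majority rule", {
  scan <- function(p) tibble::tibble(pathway = "P", p = p)
  two <- select_sig_pathways(list(a = scan(0.05), b = scan(0.2)))
  expect_false(two$risk)          # 1/2 = 0.5 is not > 0.5
  three <- select_sig_pathways(list(a = scan(0.05), b = scan(0.05),
                                    c = scan(0.2)))
  expect_true(three$risk)         # 2/3 > 0.5
  one <- select_sig_pathways(list(a = scan(0.09)))
  expect_true(one$risk)           # 1/1
  # absent from one dataset counts as not significant there
  absent <- select_sig_pathways(list(
    a = tibble::tibble(pathway = c("P", "Q"), p = c(0.01, 0.01)),
    b = tibble::tibble(pathway = "Q", p = 0.01)
  ))
  expect_equal(absent$risk[absent$pathway == "P"], FALSE)
  expect_equal(absent$risk[absent$pathway == "Q"], TRUE)
})

test_that("leading edges follow the walk extremum on both signs", {
  r <- ranked_tbl(paste0("g", 1:8), c(4, 3, 2, 1, -1, -2, -3, -4))
  up <- enrichment_score(r, c("g1", "g3", "g8"), weight = 1)
  expect_true(up$es > 0)
  i_max <- which.max(abs(up$walk))
  expect_setequal(up$leading_edge,
                  intersect(paste0("g", seq_len(i_max)), c("g1", "g3", "g8")))
  down <- enrichment_score(r, c("g6", "g7", "g8"), weight = 1)
  expect_true(down$es < 0)
  i_min <- which.max(abs(down$walk))
  expect_setequal(down$leading_edge,
                  intersect(paste0("g", i_min:8), c("g6", "g7", "g8")))
})
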