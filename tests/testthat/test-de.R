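test_that("welch table matches the textbook formula and handles degenerate groups", {
  case <- c(2.1, 1.9, 2.0, 2.2)
  ctrl <- c(1.0, 0.9, 1.1, 1.0)
  vals <- rbind(
    A = c(case, ctrl),
    B = c(1, 2, 3, 1, 1, 2, 3, 1),          # identical groups
    C = c(0, 0, 0, 0, 1, 1, 1, 1)           # zero variance, unequal means
  )
  colnames(vals) <- sprintf("s%d", 1:8)
  st <- study_from_matrix(vals, n_case = 4)
  tab <- welch_t_table(st)

  # hand-computed Welch t and Welch-Satterthwaite df
  v1 <- var(case); v2 <- var(ctrl); n <- 4
  t_hand <- (mean(case) - mean(ctrl)) / sqrt(v1 / n + v2 / n)
  df_hand <- (v1 / n + v2 / n)^2 /
    ((v1 / n)^2 / (n - 1) + (v2 / n)^2 / (n - 1))
  row_a <- tab[tab$feature == "A", ]
  expect_equal(row_a$t, t_hand, tolerance = 1e-10)
  expect_equal(row_a$df, df_hand, tolerance = 1e-10)
  expect_equal(row_a$p, t.test(case, ctrl)$p.value, tolerance = 1e-10)

  row_b <- tab[tab$feature == "B", ]
  expect_equal(row_b$t, 0)
  expect_equal(row_b$p, 1)
  expect_equal(row_b$log2fc, 0)
  expect_equal(row_b$direction, "flat")

  row_c <- tab[tab$feature == "C", ]
  expect_true(row_c$degenerate)
  expect_equal(row_c$direction, "down")
  expect_equal(row_c$p, .Machine$double.xmin)
})

test_that("welch table is shift-invariant and antisymmetric under label swap", {
  st <- make_study(n_features = 30, seed = 21)
  shifted <- st
  shifted$values <- st$values + 7.5
  expect_equal(welch_t_table(st)$t, welch_t_table(shifted)$t,
               tolerance = 1e-9)

  swapped <- st
  swapped$labels <- setNames(
    ifelse(st$labels == "case", "control", "case"), names(st$labels))
  expect_equal(welch_t_table(st)$log2fc, -welch_t_table(swapped)$log2fc)
})

test_that("moderated t shrinks toward the common variance and matches limma", {
  skip_if_not_installed("limma")
  st <- make_study(n_features = 300, n_case = 5, n_control = 5, seed = 13)
  tab <- moderated_t_table(st)

  design <- cbind(1, as.integer(st$labels == "case"))
  fit <- limma::eBayes(limma::lmFit(st$values, design))
  expect_equal(tab$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(tab$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
  expect_equal(unique(tab$d0), unname(fit$df.prior), tolerance = 1e-4)
})

test_that("identical sample variances collapse shrinkage to a single posterior", {
  # every feature has the same case and control sample variance, so the
  # prior absorbs everything (d0 = Inf) and all posteriors coincide
  base <- c(-1, 0, 1, -1, 0, 1)
  vals <- t(vapply(1:20, function(i) base + i, numeric(6)))
  rownames(vals) <- sprintf("F%02d", 1:20)
  colnames(vals) <- sprintf("s%d", 1:6)
  st <- study_from_matrix(vals, n_case = 3)
  tab <- moderated_t_table(st)
  expect_true(is.infinite(unique(tab$d0)))
  # complete shrinkage: every posterior equals the shared sample variance,
  # so the moderated t is the pooled-variance t (here all diffs are 0)
  expect_equal(tab$s2_post, rep(1, 20))
  expect_equal(tab$s0_2, rep(1, 20))
})

test_that("moderated t is calibrated on null features", {
  st <- make_study(n_features = 500, n_case = 5, n_control = 5, seed = 31)
  tab <- moderated_t_table(st)
  ks <- suppressWarnings(stats::ks.test(tab$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("too few features falls back to the Welch test with a warning", {
  st <- make_study(n_features = 5, seed = 2)
  expect_warning(tab <- moderated_t_table(st), "falling back")
  expect_equal(tab$t, welch_t_table(st)$t)
})

test_that("fisher combination reproduces closed forms", {
  t1 <- fake_de_table(c(1, 0.5, 0.25))
  t2 <- fake_de_table(c(1, 0.5, 0.8))
  meta <- fisher_combine(list(a = t1, b = t2))

  expect_equal(meta$p[meta$feature == "F01"], 1)           # p = (1, 1)
  # p = (0.5, 0.5): X2 = 2.7726, df 4 closed form e^(-x/2) (1 + x/2)
  x2 <- -2 * (log(0.5) + log(0.5))
  expect_equal(meta$x2[meta$feature == "F02"], x2, tolerance = 1e-10)
  expect_equal(meta$p[meta$feature == "F02"],
               exp(-x2 / 2) * (1 + x2 / 2), tolerance = 1e-10)
  expect_equal(meta$p[meta$feature == "F02"], 0.5966, tolerance = 1e-4)

  single <- fisher_combine(list(only = t1))
  expect_equal(single$p, t1$p, tolerance = 1e-12)   # k = 1 identity
})

test_that("fisher combination is monotone in every input p", {
  base <- fake_de_table(c(0.3, 0.3))
  for (q in c(0.2, 0.1, 0.01)) {
    lower <- fake_de_table(c(q, 0.3))
    p_base <- fisher_combine(list(a = base, b = base))$p
    p_low <- fisher_combine(list(a = lower, b = base))$p
    expect_lte(p_low[1], p_base[1])
  }
  bad <- fake_de_table(0.5)
  bad$p <- 0
  expect_error(fisher_combine(list(a = bad)), "\\(0, 1\\]")
})

test_that("fisher combination flags discordant studies and drops missing features", {
  t1 <- fake_de_table(c(0.01, 0.02), log2fc = c(1, 1))
  t2 <- fake_de_table(c(0.01, 0.02), log2fc = c(-1, 1))
  t2 <- t2[1:2, ]
  t1_extra <- rbind(t1, fake_de_table(0.5)[1, ])
  t1_extra$feature[3] <- "ONLY_IN_A"
  meta <- fisher_combine(list(a = t1_extra, b = t2))
  expect_setequal(meta$feature, c("F01", "F02"))
  expect_true(meta$discordant[meta$feature == "F01"])
  expect_false(meta$discordant[meta$feature == "F02"])
})

test_that("DE calling applies the human and rodent rules with exact boundaries", {
  tab <- fake_de_table(c(0.049, 0.05, 0.051), log2fc = c(0.1, 1.0, 2.0))
  called <- call_de(tab, p_threshold = 0.05)
  expect_equal(called$feature, "F01")

  rat <- call_de(tab, p_threshold = 0.05, fc_threshold = 2)
  expect_equal(rat$feature, "F02")   # p = .05 inclusive, |log2fc| = 1

  expect_equal(nrow(call_de(tab[0, ], 0.05)), 0)
  expect_equal(nrow(call_de(tab, p_threshold = 0)), 0)
})
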