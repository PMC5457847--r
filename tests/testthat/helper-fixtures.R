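# small deterministic fixtures built in code

make_study <- function(n_features = 20, n_case = 5, n_control = 5,
                       effects = numeric(), noise_sd = 0.5, seed = 42,
                       platform = "mRNA", prefix = "G") {
  ids <- sprintf("%s%03d", prefix, seq_len(n_features))
  simulate_expression_study(ids, effects, design = c(n_case, n_control),
                            noise_sd = noise_sd, seed = seed,
                            study_id = "fix", platform = platform)
}

study_from_matrix <- function(vals, n_case, platform = "mRNA") {
  labels <- rep(c("case", "control"),
                c(n_case, ncol(vals) - n_case))
  names(labels) <- colnames(vals)
  expression_study(vals, labels, study_id = "manual", platform = platform)
}

# a de_table-shaped tibble for threshold-rule tests
fake_de_table <- function(p, log2fc = rep(0.5, length(p))) {
  tibble::tibble(
    feature = sprintf("F%02d", seq_along(p)),
    log2fc = log2fc,
    se = 0.1, t = 1, df = 10, p = p, p_adj = mirpathnet::bh_adjust(p),
    direction = ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "flat")),
    degenerate = FALSE
  )
}

small_bundle_config <- function(seed = 7) {
  simulation_config(
    n_genes = 400, n_mirnas = 40, n_pathways = 6, pathway_size = c(10, 18),
    fraction_de_genes = 0.12, fraction_de_mirnas = 0.15,
    targets_per_mirna = 12, n_rat_mirnas = 25, n_shared_de = 2,
    seed = seed
  )
}

random_simple_graph <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}
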