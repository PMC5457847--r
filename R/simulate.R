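#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline is built for: two mRNA
#' studies of 9 case vs 9 control pancreatic-tissue samples, one miRNA study
#' of 33 case vs 58 control samples, a validated miRNA-target map, a KEGG-like
#' pathway collection with overlapping membership, and a scale-free PPI
#' network. Differential features are planted as an additive log2 shift of
#' `effect_size` (default 1.0) on Gaussian noise with `noise_sd` (default
#' 0.5); each planted risk pair couples one miRNA to one pathway whose member
#' genes share a common case-shift and which the miRNA's targets over-populate.
#'
#' @param n_genes,n_mirnas Universe sizes.
#' @param mrna_design List of `c(case, control)` sizes, one per mRNA study.
#' @param mirna_design `c(case, control)` sizes of the miRNA study.
#' @param n_pathways Number of pathways (includes the planted ones).
#' @param pathway_size `c(min, max)` pathway sizes.
#' @param fraction_de_genes,fraction_de_mirnas Planted DE fractions.
#' @param effect_size Mean log2 case shift of planted DE features.
#' @param noise_sd Within-group standard deviation (log2 scale).
#' @param n_planted_risk_pairs Number of planted (miRNA, pathway) risk pairs.
#' @param targets_per_mirna Expected distinct targets per miRNA.
#' @param planted_target_overlap Fraction of a planted miRNA's targets that
#'   fall inside its planted pathway.
#' @param ppi_attachment Preferential-attachment parameter of the PPI model.
#' @param rat_design `c(case, control)` sizes of the companion rat miRNA
#'   study used by the cross-species stage.
#' @param n_rat_mirnas Rat miRNA universe size.
#' @param n_shared_de Planted DE miRNAs shared (same direction) between the
#'   human and rat studies.
#' @param rat_effect_size Log2 case shift of rat DE miRNAs (the rat calling
#'   rule requires a linear fold change of at least 2).
#' @param baseline_mean,baseline_sd Distribution of per-feature baseline
#'   log2 intensities.
#' @param seed Integer seed; every generator below is deterministic in it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2400,
                              n_mirnas = 150,
                              mrna_design = list(c(9, 9), c(9, 9)),
                              mirna_design = c(33, 58),
                              n_pathways = 10,
                              pathway_size = c(15, 30),
                              fraction_de_genes = 0.10,
                              fraction_de_mirnas = 0.10,
                              effect_size = 1.0,
                              noise_sd = 0.5,
                              n_planted_risk_pairs = 2,
                              targets_per_mirna = 25,
                              planted_target_overlap = 0.6,
                              ppi_attachment = 2,
                              rat_design = c(4, 4),
                              n_rat_mirnas = 60,
                              n_shared_de = 3,
                              rat_effect_size = 1.5,
                              baseline_mean = 6,
                              baseline_sd = 1.5,
                              seed = 1) {
  cfg <- list(
    n_genes = n_genes, n_mirnas = n_mirnas, mrna_design = mrna_design,
    mirna_design = mirna_design, n_pathways = n_pathways,
    pathway_size = pathway_size, fraction_de_genes = fraction_de_genes,
    fraction_de_mirnas = fraction_de_mirnas, effect_size = effect_size,
    noise_sd = noise_sd, n_planted_risk_pairs = n_planted_risk_pairs,
    targets_per_mirna = targets_per_mirna,
    planted_target_overlap = planted_target_overlap,
    ppi_attachment = ppi_attachment, rat_design = rat_design,
    n_rat_mirnas = n_rat_mirnas, n_shared_de = n_shared_de,
    rat_effect_size = rat_effect_size,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd, seed = seed
  )
  counts <- c(cfg$n_genes, cfg$n_mirnas, cfg$n_pathways,
              cfg$n_planted_risk_pairs, cfg$targets_per_mirna)
  if (any(counts <= 0)) stop("counts must be positive", call. = FALSE)
  if (cfg$fraction_de_genes < 0 || cfg$fraction_de_genes >= 1 ||
      cfg$fraction_de_mirnas < 0 || cfg$fraction_de_mirnas >= 1) {
    stop("DE fractions must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$effect_size <= 0) stop("effect_size must be > 0", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

# deterministic per-stage seed fan-out from one global seed
stage_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k)
}

#' Simulate one labeled expression study
#'
#' Control samples are drawn as `Normal(baseline, noise_sd)` per feature;
#' case samples additionally receive the signed log2 effect given in
#' `effects`. Everything is deterministic for a fixed seed.
#'
#' @param feature_ids Character vector of feature ids.
#' @param effects Named numeric vector of signed log2 shifts; names must be
#'   a subset of `feature_ids`. Features absent from it get effect 0.
#' @param design `c(n_case, n_control)`.
#' @param noise_sd Within-group standard deviation; must be positive.
#' @param baseline Either a single number or a named per-feature baseline.
#' @param seed Integer seed.
#' @param study_id,platform Passed to [expression_study()].
#' @return An [expression_study].
#' @export
simulate_expression_study <- function(feature_ids, effects = numeric(),
                                      design = c(9, 9), noise_sd = 0.5,
                                      baseline = 6, seed = 1,
                                      study_id = "sim", platform = "mRNA") {
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (length(effects) && !all(names(effects) %in% feature_ids)) {
    stop("effects defined for unknown features", call. = FALSE)
  }
  n_case <- design[[1]]; n_ctrl <- design[[2]]
  n <- length(feature_ids)
  eff <- setNames(numeric(n), feature_ids)
  eff[names(effects)] <- effects
  if (length(baseline) == 1) {
    base <- rep(as.numeric(baseline), n)
  } else {
    base <- as.numeric(baseline[feature_ids])
  }
  set.seed(seed)
  vals <- matrix(rnorm(n * (n_case + n_ctrl), mean = base, sd = noise_sd),
                 nrow = n)
  vals[, seq_len(n_case)] <- vals[, seq_len(n_case)] + eff
  colnames(vals) <- c(sprintf("%s_case_%02d", study_id, seq_len(n_case)),
                      sprintf("%s_ctrl_%02d", study_id, seq_len(n_ctrl)))
  rownames(vals) <- feature_ids
  labels <- setNames(rep(c("case", "control"), c(n_case, n_ctrl)),
                     colnames(vals))
  expression_study(vals, labels, study_id = study_id, platform = platform)
}

#' Simulate a scale-free PPI network by preferential attachment
#'
#' @param n_nodes Number of proteins.
#' @param attachment Edges added per new node (Barabasi-Albert `m`).
#' @param seed Integer seed.
#' @param node_ids Optional node names (defaults to `P1..Pn`).
#' @return A `ppi_network` tibble; the graph is connected with no self-loops
#'   or duplicate edges.
#' @export
simulate_scale_free_ppi <- function(n_nodes, attachment = 2, seed = 1,
                                    node_ids = NULL) {
  if (attachment < 1 || n_nodes <= attachment) {
    stop("need n_nodes > attachment >= 1", call. = FALSE)
  }
  if (is.null(node_ids)) node_ids <- sprintf("P%d", seq_len(n_nodes))
  stopifnot(length(node_ids) == n_nodes)
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, m = attachment, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  ppi_network(node_ids[el[, 1]], node_ids[el[, 2]])
}

#' Simulate a complete analysis bundle with planted ground truth
#'
#' Generates expression studies, pathway collection, miRNA-target map, PPI
#' network and a rat miRNA study, together with a `truth` record listing the
#' planted DE features, enriched pathways, (miRNA, pathway) risk pairs and
#' (miRNA, gene, pathway) triples. Construction guarantees the truth record's
#' consistency invariants: every planted triple's gene belongs to its pathway
#' and to the planted DE genes, and its (miRNA, gene) pair is in the target
#' map.
#'
#' Identifiability choices (documented in the methods vignette): planted
#' pathways draw their members from disjoint gene pools and are the only
#' pathways containing shifted genes; extra DE genes live outside all
#' pathways; background miRNAs never target planted-pathway genes. This
#' makes the planted risk structure the unique signal a correct pipeline can
#' recover.
#'
#' @param cfg A [simulation_config()].
#' @return A list with elements `mrna_studies` (list), `mirna_study`,
#'   `rat_study`, `pathways` (`gene_set_collection`), `targets`
#'   (`target_map`), `ppi` (`ppi_network`), and `truth`.
#' @export
simulate_bundle <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  mirnas <- sprintf("hsa-miR-%03d", seq_len(cfg$n_mirnas))
  n_plant <- cfg$n_planted_risk_pairs

  # -- pathways -------------------------------------------------------------
  set.seed(stage_seed(cfg$seed, 1))
  sizes <- sample(seq(cfg$pathway_size[1], cfg$pathway_size[2]),
                  cfg$n_pathways, replace = TRUE)
  if (n_plant > cfg$n_pathways) stop("more planted pairs than pathways", call. = FALSE)
  if (sum(sizes[seq_len(n_plant)]) > cfg$n_genes) {
    stop("gene universe too small for the planted pathways", call. = FALSE)
  }
  pool <- sample(genes)  # random order, then carve disjoint planted pools
  sets <- vector("list", cfg$n_pathways)
  names(sets) <- sprintf("PATH_%02d", seq_len(cfg$n_pathways))
  used <- 0
  for (i in seq_len(n_plant)) {
    sets[[i]] <- sort(pool[(used + 1):(used + sizes[i])])
    used <- used + sizes[i]
  }
  planted_genes <- unique(unlist(sets[seq_len(n_plant)]))
  background_pool <- setdiff(genes, planted_genes)
  for (i in seq_len(cfg$n_pathways)) {
    if (i <= n_plant) next
    sets[[i]] <- sort(sample(background_pool, sizes[i]))
  }
  pathways <- gene_set_collection(sets, source_tag = "synthetic")
  planted_paths <- names(sets)[seq_len(n_plant)]

  # -- planted DE genes -----------------------------------------------------
  set.seed(stage_seed(cfg$seed, 2))
  n_de_genes <- round(cfg$fraction_de_genes * cfg$n_genes)
  path_dir <- rep_len(c(1, -1), n_plant)  # alternate up/down pathway shifts
  de_genes <- tibble::tibble(
    gene = unlist(sets[seq_len(n_plant)]),
    direction_sign = rep(path_dir, times = lengths(sets[seq_len(n_plant)]))
  ) |> dplyr::distinct(.data$gene, .keep_all = TRUE)
  n_extra <- max(0L, n_de_genes - nrow(de_genes))
  in_any_pathway <- unique(unlist(sets))
  free_genes <- setdiff(genes, in_any_pathway)
  if (n_extra > length(free_genes)) n_extra <- length(free_genes)
  extra <- sample(free_genes, n_extra)
  de_genes <- dplyr::bind_rows(
    de_genes,
    tibble::tibble(gene = extra,
                   direction_sign = sample(c(-1, 1), n_extra, replace = TRUE))
  )
  gene_effects <- setNames(de_genes$direction_sign * cfg$effect_size,
                           de_genes$gene)

  # -- planted DE miRNAs ----------------------------------------------------
  set.seed(stage_seed(cfg$seed, 3))
  n_de_mir <- max(n_plant, round(cfg$fraction_de_mirnas * cfg$n_mirnas))
  planted_mirnas <- mirnas[seq_len(n_plant)]
  other_de <- sample(setdiff(mirnas, planted_mirnas), n_de_mir - n_plant)
  de_mirnas <- tibble::tibble(
    mirna = c(planted_mirnas, other_de),
    # a planted regulator shifts opposite to its pathway (canonical repression)
    direction_sign = c(-path_dir,
                       sample(c(-1, 1), n_de_mir - n_plant, replace = TRUE))
  )
  mirna_effects <- setNames(de_mirnas$direction_sign * cfg$effect_size,
                            de_mirnas$mirna)

  # -- target map -----------------------------------------------------------
  set.seed(stage_seed(cfg$seed, 4))
  pairs <- list()
  for (i in seq_along(mirnas)) {
    m <- mirnas[i]
    if (m %in% planted_mirnas) {
      pw <- sets[[which(planted_mirnas == m)]]
      k_in <- max(1L, round(cfg$planted_target_overlap * cfg$targets_per_mirna))
      k_in <- min(k_in, length(pw))
      k_out <- max(0L, cfg$targets_per_mirna - k_in)
      tg <- c(sample(pw, k_in),
              sample(background_pool, min(k_out, length(background_pool))))
    } else {
      k <- max(5L, stats::rpois(1, cfg$targets_per_mirna))
      tg <- sample(background_pool, min(k, length(background_pool)))
    }
    pairs[[i]] <- tibble::tibble(mirna = m, gene = tg)
  }
  pairs <- dplyr::bind_rows(pairs)
  targets <- target_map(pairs$mirna, pairs$gene, provenance = "validated")

  # -- expression studies ---------------------------------------------------
  set.seed(stage_seed(cfg$seed, 5))
  gene_base <- setNames(rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd),
                        genes)
  mirna_base <- setNames(rnorm(cfg$n_mirnas, cfg$baseline_mean, cfg$baseline_sd),
                         mirnas)
  mrna_studies <- lapply(seq_along(cfg$mrna_design), function(j) {
    simulate_expression_study(
      genes, gene_effects, design = cfg$mrna_design[[j]],
      noise_sd = cfg$noise_sd, baseline = gene_base,
      seed = stage_seed(cfg$seed, 10 + j),
      study_id = sprintf("mrna_%d", j), platform = "mRNA"
    )
  })
  names(mrna_studies) <- vapply(mrna_studies, `[[`, character(1), "study_id")
  mirna_study <- simulate_expression_study(
    mirnas, mirna_effects, design = cfg$mirna_design,
    noise_sd = cfg$noise_sd, baseline = mirna_base,
    seed = stage_seed(cfg$seed, 20), study_id = "mirna_1", platform = "miRNA"
  )

  # -- rat miRNA study (shares some DE miRNAs with the human study) ---------
  set.seed(stage_seed(cfg$seed, 6))
  n_shared <- min(cfg$n_shared_de, n_de_mir)
  shared_human <- de_mirnas$mirna[seq_len(n_shared)]
  rat_of <- function(x) sub("^hsa-", "rno-", x)
  rat_features <- unique(c(
    rat_of(shared_human),
    rat_of(sample(setdiff(mirnas, shared_human),
                  min(cfg$n_rat_mirnas, cfg$n_mirnas) - n_shared))
  ))
  rat_effects <- setNames(
    de_mirnas$direction_sign[seq_len(n_shared)] * cfg$rat_effect_size,
    rat_of(shared_human)
  )
  rat_study <- simulate_expression_study(
    rat_features, rat_effects, design = cfg$rat_design,
    noise_sd = cfg$noise_sd, baseline = cfg$baseline_mean,
    seed = stage_seed(cfg$seed, 21), study_id = "rat_mirna", platform = "miRNA"
  )

  # -- PPI ------------------------------------------------------------------
  ppi <- simulate_scale_free_ppi(cfg$n_genes, cfg$ppi_attachment,
                                 seed = stage_seed(cfg$seed, 7),
                                 node_ids = genes)

  # -- truth record ---------------------------------------------------------
  sign_lab <- function(s) ifelse(s > 0, "up", "down")
  triples <- purrr::map_dfr(seq_len(n_plant), function(i) {
    m <- planted_mirnas[i]
    pw_name <- planted_paths[i]
    tg <- dplyr::filter(tibble::as_tibble(targets), .data$mirna == m)$gene
    g <- intersect(tg, sets[[pw_name]])
    tibble::tibble(mirna = m, gene = sort(g), pathway = pw_name)
  })
  truth <- list(
    de_genes = tibble::tibble(gene = de_genes$gene,
                              direction = sign_lab(de_genes$direction_sign)),
    de_mirnas = tibble::tibble(mirna = de_mirnas$mirna,
                               direction = sign_lab(de_mirnas$direction_sign)),
    pathways = planted_paths,
    risk_pairs = tibble::tibble(mirna = planted_mirnas,
                                pathway = planted_paths),
    risk_genes = sort(planted_genes),
    triples = triples,
    shared_demirs = shared_human
  )
  validate_truth(truth, pathways, targets)

  list(mrna_studies = mrna_studies, mirna_study = mirna_study,
       rat_study = rat_study, pathways = pathways, targets = targets,
       ppi = ppi, truth = truth, config = cfg)
}

# internal consistency check of a truth record against the generated inputs
validate_truth <- function(truth, pathways, targets) {
  tr <- truth$triples
  if (!nrow(tr)) return(invisible(TRUE))
  pair_key <- paste(targets$mirna, targets$gene)
  ok_target <- paste(tr$mirna, tr$gene) %in% pair_key
  ok_member <- purrr::map2_lgl(tr$gene, tr$pathway,
                               ~ .x %in% pathways[[.y]])
  ok_de <- tr$gene %in% truth$de_genes$gene &
    tr$mirna %in% truth$de_mirnas$mirna
  if (!all(ok_target & ok_member & ok_de)) {
    stop("inconsistent truth record", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a simulated bundle to a directory in the package's standard formats
#'
#' @param bundle Result of [simulate_bundle()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in bundle$mrna_studies) {
    write_expression_matrix(s, file.path(dir, paste0(s$study_id, ".tsv")))
  }
  write_expression_matrix(bundle$mirna_study, file.path(dir, "mirna_1.tsv"))
  write_expression_matrix(bundle$rat_study, file.path(dir, "rat_mirna.tsv"))
  write_gmt(bundle$pathways, file.path(dir, "pathways.gmt"))
  write_interaction_table(bundle$targets, file.path(dir, "targets.tsv"))
  write_edge_list(bundle$ppi, file.path(dir, "ppi.tsv"))
  write.table(bundle$truth$triples, file.path(dir, "truth_triples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
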