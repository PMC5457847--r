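#' Pipeline configuration
#'
#' Collects every stage threshold (defaults are the standard published
#' rules: DE at raw p < .05, risk pathways at enrichment p < .1 in strictly
#' more than half of the datasets, miRNA-pathway pairs at adjusted p < .05,
#' the rodent rule at p <= .05 and fold change >= 2) together with the GSEA
#' and cross-validation settings and a single global seed that fans out
#' deterministically to every stage.
#'
#' @param simulate A [simulation_config()] describing the synthetic bundle,
#'   or `NULL` when a pre-built bundle is passed to [run_pipeline()].
#' @param de_method `"welch"` or `"moderated"` per-study test.
#' @param de_p DE p-value threshold (strict `<`, raw p).
#' @param gsea_p Enrichment p threshold for the risk-pathway rule.
#' @param dataset_fraction Fraction of datasets that must be exceeded
#'   (strictly) for a risk pathway.
#' @param pair_p miRNA-pathway pair significance threshold (BH-adjusted).
#' @param rat_fc,rat_p The rodent DE rule: linear fold change `>= rat_fc`
#'   and `p <= rat_p`.
#' @param n_perm,gsea_weight GSEA permutations and hit-weight exponent.
#' @param cv_k Cross-validation folds for biomarker AUC.
#' @param seed Global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = simulation_config(),
                            de_method = c("welch", "moderated"),
                            de_p = 0.05, gsea_p = 0.1,
                            dataset_fraction = 0.5, pair_p = 0.05,
                            rat_fc = 2.0, rat_p = 0.05,
                            n_perm = 1000, gsea_weight = 1,
                            cv_k = 5, seed = 1) {
  de_method <- match.arg(de_method)
  stopifnot(de_p >= 0, de_p <= 1, gsea_p > 0, gsea_p <= 1,
            dataset_fraction >= 0, dataset_fraction < 1,
            pair_p > 0, pair_p <= 1, rat_p > 0, rat_p <= 1, rat_fc >= 1,
            n_perm >= 10, cv_k >= 2)
  if (!is.null(simulate)) {
    simulate$seed <- seed
    class(simulate) <- "simulation_config"
  }
  structure(
    list(simulate = simulate, de_method = de_method, de_p = de_p,
         gsea_p = gsea_p, dataset_fraction = dataset_fraction,
         pair_p = pair_p, rat_fc = rat_fc, rat_p = rat_p, n_perm = n_perm,
         gsea_weight = gsea_weight, cv_k = cv_k, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full miRNA-mRNA-pathway analysis
#'
#' Stages, in order: per-study differential expression and Fisher
#' combination across the mRNA studies; DE calling (human rule); GSEA per
#' mRNA study and consensus risk-pathway selection; core (leading-edge)
#' genes of the risk pathways; risk genes as core intersect DEGs;
#' hypergeometric miRNA-pathway pairs with BH adjustment; triple assembly;
#' network construction with PPI overlay and topology; cross-validated
#' single-feature AUC for the network's miRNAs and risk genes; and the
#' cross-species DEmiR comparison against the rat study. Empty intermediate
#' sets downgrade later stages to no-ops with warnings.
#'
#' @param config A [pipeline_config()].
#' @param bundle Optional pre-built input bundle in the shape returned by
#'   [simulate_bundle()]; when `NULL` the configured simulation is run.
#' @param out_dir Optional directory; when given, every stage table is
#'   written there as TSV and the network as SIF + GraphML.
#' @return A list of class `pipeline_result` with all stage outputs, a
#'   `summary` tibble of stage counts and a `manifest` of thresholds and
#'   seeds.
#' @export
run_pipeline <- function(config = pipeline_config(), bundle = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(bundle)) {
    if (is.null(config$simulate)) {
      stop("no bundle given and no simulation configured", call. = FALSE)
    }
    bundle <- simulate_bundle(config$simulate)
  }

  de_fun <- if (config$de_method == "welch") welch_t_table else moderated_t_table

  # -- differential expression ---------------------------------------------
  de_tables <- lapply(bundle$mrna_studies, de_fun)
  meta <- fisher_combine(de_tables)
  degs <- call_de(meta, p_threshold = config$de_p)
  mir_table <- de_fun(bundle$mirna_study)
  demirs <- call_de(mir_table, p_threshold = config$de_p)

  # -- GSEA and risk pathways ----------------------------------------------
  scans <- lapply(seq_along(bundle$mrna_studies), function(j) {
    gsea_scan(bundle$mrna_studies[[j]], bundle$pathways,
              weight = config$gsea_weight, n_perm = config$n_perm,
              seed = stage_seed(config$seed, 30 + j))
  })
  names(scans) <- names(bundle$mrna_studies)
  sig <- select_sig_pathways(scans, p_threshold = config$gsea_p,
                             dataset_fraction = config$dataset_fraction)
  risk_paths <- sig$pathway[sig$risk]
  core <- core_genes(scans, sig)

  # -- risk genes, pairs, triples, network ---------------------------------
  risk_genes <- identify_risk_genes(core, degs, bundle$pathways, risk_paths)
  background <- intersect(
    rownames(bundle$mrna_studies[[1]]$values),
    union(unique(tibble::as_tibble(bundle$targets)$gene),
          unique(unlist(as.list(bundle$pathways))))
  )
  pairs <- test_mirna_pathways(
    demirs$feature, bundle$targets, risk_paths, bundle$pathways,
    background, p_threshold = config$pair_p
  )
  triples <- build_triples(demirs, risk_genes, risk_paths, bundle$targets,
                           bundle$pathways)
  concord <- classify_concordance(triples)
  network <- if (nrow(triples)) build_network(triples, bundle$ppi) else NULL
  topo_composite <- if (!is.null(network)) node_topology(network) else NULL
  topo_ppi <- if (nrow(risk_genes)) {
    node_topology(bundle$ppi) |>
      dplyr::filter(.data$node %in% risk_genes$gene)
  } else NULL

  # -- biomarker evaluation -------------------------------------------------
  mir_feats <- unique(triples$mirna)
  gene_feats <- unique(triples$gene)
  auc_mirnas <- if (length(mir_feats)) {
    evaluate_biomarkers(bundle$mirna_study, mir_feats, k = config$cv_k,
                        seed = stage_seed(config$seed, 40))
  } else NULL
  auc_genes <- if (length(gene_feats)) {
    purrr::imap_dfr(bundle$mrna_studies, function(st, nm) {
      evaluate_biomarkers(st, gene_feats, k = config$cv_k,
                          seed = stage_seed(config$seed, 41)) |>
        dplyr::mutate(study = nm, .before = 1)
    })
  } else NULL

  # -- cross-species --------------------------------------------------------
  shared <- NULL
  if (!is.null(bundle$rat_study)) {
    rat_table <- welch_t_table(bundle$rat_study)
    rat_demirs <- call_de(rat_table, p_threshold = config$rat_p,
                          fc_threshold = config$rat_fc)
    shared <- shared_demirs(demirs, rat_demirs)
  }

  summary <- tibble::tibble(
    stage = c("DEGs", "DEmiRs", "pathways_tested", "risk_pathways",
              "core_genes", "risk_genes", "mirna_pathway_pairs",
              "significant_pairs", "triples", "unique_pairs_opposite",
              "unique_pairs_same", "ppi_edges_overlaid", "shared_demirs"),
    n = c(nrow(degs), nrow(demirs), nrow(sig), length(risk_paths),
          length(core), nrow(risk_genes), nrow(pairs),
          sum(pairs$significant), nrow(triples), concord$opposite,
          concord$same,
          if (is.null(network)) 0L else sum(network$edges$type == "ppi"),
          if (is.null(shared)) 0L else nrow(shared))
  )
  manifest <- list(
    seed = config$seed, de_method = config$de_method, de_p = config$de_p,
    gsea_p = config$gsea_p, dataset_fraction = config$dataset_fraction,
    pair_p = config$pair_p, rat_fc = config$rat_fc, rat_p = config$rat_p,
    n_perm = config$n_perm, gsea_weight = config$gsea_weight,
    cv_k = config$cv_k,
    n_mrna_studies = length(bundle$mrna_studies),
    n_features = vapply(c(bundle$mrna_studies,
                          list(mirna = bundle$mirna_study)),
                        function(s) nrow(s$values), numeric(1))
  )

  result <- structure(
    list(bundle = bundle, de_tables = de_tables, meta = meta, degs = degs,
         mirna_de = mir_table, demirs = demirs, gsea = scans,
         sig_pathways = sig, core_genes = core, risk_genes = risk_genes,
         pairs = pairs, triples = triples, concordance = concord,
         network = network, topology_composite = topo_composite,
         topology_ppi = topo_ppi, auc_mirnas = auc_mirnas,
         auc_genes = auc_genes, shared_demirs = shared,
         summary = summary, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Write every stage table of a pipeline run to a directory
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(tbl, name) {
    if (is.null(tbl)) return()
    tbl <- as.data.frame(tbl)
    list_cols <- vapply(tbl, is.list, logical(1))
    for (col in names(tbl)[list_cols]) {
      tbl[[col]] <- vapply(tbl[[col]], paste, character(1), collapse = ";")
    }
    write.table(tbl, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wt(result$meta, "meta_de")
  wt(result$degs, "degs")
  wt(result$mirna_de, "mirna_de")
  wt(result$demirs, "demirs")
  for (nm in names(result$gsea)) wt(result$gsea[[nm]], paste0("gsea_", nm))
  wt(result$sig_pathways, "sig_pathways")
  wt(result$risk_genes, "risk_genes")
  wt(result$pairs, "mirna_pathway_pairs")
  wt(result$triples, "triples")
  wt(result$topology_composite, "topology_composite")
  wt(result$topology_ppi, "topology_ppi_risk_genes")
  wt(result$auc_mirnas, "auc_mirnas")
  wt(result$auc_genes, "auc_genes")
  wt(result$shared_demirs, "shared_demirs")
  wt(result$summary, "summary")
  if (!is.null(result$network)) {
    write_network(result$network, file.path(dir, "network.sif"), "sif")
    write_network(result$network, file.path(dir, "network.graphml"), "graphml")
  }
  writeLines(paste(names(unlist(result$manifest)),
                   unlist(result$manifest), sep = "\t"),
             file.path(dir, "manifest.tsv"))
  invisible(dir)
}
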