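#' Construct an expression study
#'
#' A lightweight container for one labeled case/control expression matrix
#' (log2-scale intensities), the basic unit every analysis step consumes.
#'
#' @param values Numeric matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids).
#' @param labels Character vector of `"case"`/`"control"`, one per sample,
#'   either named by sample id or in column order.
#' @param study_id Short identifier for the study.
#' @param platform `"mRNA"` or `"miRNA"`.
#' @return An object of class `expression_study` with elements `values`,
#'   `labels` (named character), `study_id`, `platform`.
#' @export
expression_study <- function(values, labels, study_id = "study",
                             platform = c("mRNA", "miRNA")) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs feature rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("feature ids must be unique", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("sample ids must be unique", call. = FALSE)
  }
  if (anyNA(values)) stop("expression values must not contain NA", call. = FALSE)
  lab_names <- names(labels)
  labels <- as.character(labels)
  names(labels) <- lab_names
  if (is.null(names(labels))) {
    if (length(labels) != ncol(values)) {
      stop("`labels` length must equal the number of samples", call. = FALSE)
    }
    names(labels) <- colnames(values)
  }
  missing_lab <- setdiff(colnames(values), names(labels))
  if (length(missing_lab)) {
    stop("unlabeled sample(s): ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  }
  labels <- labels[colnames(values)]
  if (!all(labels %in% c("case", "control"))) {
    stop('labels must be "case" or "control"', call. = FALSE)
  }
  if (sum(labels == "case") < 2 || sum(labels == "control") < 2) {
    stop("need at least 2 case and 2 control samples", call. = FALSE)
  }
  structure(
    list(values = values, labels = labels, study_id = study_id,
         platform = platform),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "<expression_study '%s'> %s platform: %d features x %d samples (%d case / %d control)\n",
    x$study_id, x$platform, nrow(x$values), ncol(x$values),
    sum(x$labels == "case"), sum(x$labels == "control")
  ))
  invisible(x)
}

#' @export
#' @rdname expression_study
#' @param x An `expression_study`.
#' @param ... Unused.
tidy.expression_study <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "sample", values_to = "value") |>
    dplyr::mutate(group = unname(x$labels[.data$sample]))
}

case_idx <- function(study) which(study$labels == "case")
control_idx <- function(study) which(study$labels == "control")

#' Read a tab-separated expression matrix
#'
#' Reads a TSV whose header row holds sample ids and whose first column holds
#' feature/probe ids, then applies the standard microarray preprocessing:
#' features whose fraction of missing cells exceeds `max_missing_fraction`
#' are dropped (default: any missing cell drops the feature), remaining
#' missing cells are imputed by the feature mean, and rows sharing a feature
#' id are collapsed to their element-wise mean so each feature appears once.
#'
#' @param path Path to the TSV file. Missing cells are the token `NA`.
#' @param labels Named character vector mapping sample id to
#'   `"case"`/`"control"`; every sample in the file must be labeled.
#' @param platform `"mRNA"` or `"miRNA"`.
#' @param study_id Study identifier; defaults to the file name.
#' @param max_missing_fraction Features with a larger fraction of missing
#'   cells are dropped. Default 0.
#' @return An [expression_study].
#' @export
read_expression_matrix <- function(path, labels, platform = c("mRNA", "miRNA"),
                                   study_id = NULL,
                                   max_missing_fraction = 0) {
  platform <- match.arg(platform)
  if (is.null(study_id)) study_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = "NA")
  if (ncol(raw) < 2) stop("matrix needs a feature column and >=1 sample", call. = FALSE)
  feats <- raw[[1]]
  num <- raw[, -1, drop = FALSE]
  samples <- colnames(num)
  vals <- suppressWarnings(vapply(num, as.numeric, numeric(nrow(num))))
  vals <- matrix(vals, nrow = nrow(num), dimnames = list(NULL, samples))
  bad <- !is.na(as.matrix(num)) & is.na(vals)
  if (any(bad)) {
    stop(sprintf("non-numeric cell at data row %d, sample '%s'",
                 which(rowSums(bad) > 0)[1],
                 samples[which(colSums(bad) > 0)[1]]), call. = FALSE)
  }

  # missing-value screening, then probe combination (row means per feature id)
  miss_frac <- rowMeans(is.na(vals))
  keep <- miss_frac <= max_missing_fraction
  vals <- vals[keep, , drop = FALSE]
  feats <- feats[keep]
  if (anyNA(vals)) {
    rm <- rowMeans(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- rm[idx[, 1]]
  }
  if (anyDuplicated(feats)) {
    first <- !duplicated(feats)
    grp <- match(feats, feats[first])
    collapsed <- rowsum(vals, grp, reorder = TRUE) / as.vector(table(grp))
    vals <- collapsed
    rownames(vals) <- feats[first]
  } else {
    rownames(vals) <- feats
  }
  expression_study(vals, labels, study_id = study_id, platform = platform)
}

#' Write an expression study as a TSV matrix
#'
#' @param study An [expression_study].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(study, path) {
  df <- data.frame(feature = rownames(study$values), study$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member genes, tab-separated.
#' Duplicate members within a line are dropped; duplicate set names are an
#' error.
#'
#' @param path Path to a GMT file.
#' @param source_tag Optional provenance tag stored as an attribute.
#' @return A named list of character vectors of class `gene_set_collection`.
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i),
           call. = FALSE)
    }
    nm <- parts[[1]]
    if (nm %in% names(sets)) {
      stop(sprintf("duplicate gene set name '%s' at line %d", nm, i),
           call. = FALSE)
    }
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop(sprintf("empty gene set '%s' at line %d", nm, i), call. = FALSE)
    }
    sets[[nm]] <- members
  }
  gene_set_collection(sets, source_tag)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
gene_set_collection <- function(sets, source_tag = "user") {
  stopifnot(is.list(sets))
  if (length(sets)) {
    stopifnot(!is.null(names(sets)), all(nzchar(names(sets))),
              !anyDuplicated(names(sets)))
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (any(lengths(sets) == 0)) stop("gene sets must be nonempty", call. = FALSE)
  }
  structure(sets, class = c("gene_set_collection", "list"),
            source_tag = source_tag)
}

#' Write gene sets in GMT format
#'
#' @param sets A `gene_set_collection` or named list.
#' @param path Output path.
#' @param descriptions Optional per-set description column; defaults to "na".
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read or build a miRNA-target interaction table
#'
#' @param path TSV with two columns: miRNA id, gene id (header optional,
#'   detected by the literal header `mirna<TAB>gene`).
#' @param provenance `"validated"` or `"predicted"`.
#' @return A tibble of class `target_map` with columns `mirna`, `gene`
#'   (unique pairs).
#' @export
read_interaction_table <- function(path, provenance = c("validated", "predicted")) {
  provenance <- match.arg(provenance)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(tolower(lines[[1]]), "mirna\tgene")) {
    lines <- lines[-1]
  }
  if (!length(lines)) return(target_map(character(), character(), provenance))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 2
  if (!all(ok)) {
    stop(sprintf("interaction table parse error at line %d", which(!ok)[1]),
         call. = FALSE)
  }
  target_map(vapply(parts, `[[`, character(1), 1),
             vapply(parts, `[[`, character(1), 2), provenance)
}

#' @rdname read_interaction_table
#' @param mirna,gene Character vectors of equal length.
#' @export
target_map <- function(mirna, gene, provenance = "validated") {
  tbl <- tibble::tibble(mirna = as.character(mirna),
                        gene = as.character(gene)) |>
    dplyr::distinct()
  structure(tbl, class = c("target_map", class(tbl)), provenance = provenance)
}

#' Per-miRNA distinct target counts (the K_i of the hypergeometric test)
#'
#' @param targets A `target_map`.
#' @return Tibble with columns `mirna`, `k`.
#' @export
target_counts <- function(targets) {
  tibble::as_tibble(targets) |>
    dplyr::count(.data$mirna, name = "k")
}

#' @export
write_interaction_table <- function(targets, path) {
  write.table(as.data.frame(targets)[, c("mirna", "gene")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("mirna", "gene"))
  invisible(path)
}

#' Read an undirected PPI edge list
#'
#' Two tab-separated gene-id columns per row. Self-loops are removed and
#' reversed duplicates collapsed.
#'
#' @param path Path to the TSV edge list (no header).
#' @return A tibble of class `ppi_network` with columns `a`, `b`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(ppi_network(character(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 2
  if (!all(ok)) {
    stop(sprintf("edge list parse error at line %d", which(!ok)[1]),
         call. = FALSE)
  }
  ppi_network(vapply(parts, `[[`, character(1), 1),
              vapply(parts, `[[`, character(1), 2))
}

#' @rdname read_edge_list
#' @param a,b Character vectors of interacting gene ids.
#' @export
ppi_network <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- lo != hi
  tbl <- tibble::tibble(a = lo[keep], b = hi[keep]) |> dplyr::distinct()
  structure(tbl, class = c("ppi_network", class(tbl)))
}

#' @export
write_edge_list <- function(ppi, path) {
  write.table(as.data.frame(ppi)[, c("a", "b")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a regulatory network to SIF or GraphML
#'
#' SIF lines use the interaction tokens `targets`, `member_of` and `ppi`.
#' GraphML (written via igraph) carries node attributes `type` and
#' `direction` and the edge attribute `type`; a GraphML round trip
#' reproduces node and edge sets exactly.
#'
#' @param net A `regulatory_network` (see [build_network()]).
#' @param path Output path.
#' @param dialect `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("sif", "graphml")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(net, "regulatory_network"))
  if (dialect == "sif") {
    lines <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$type, net$edges$to)
    writeLines(lines, path)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back a GraphML regulatory-network export
#'
#' @param path Path written by [write_network()] with `dialect = "graphml"`.
#' @return A `regulatory_network`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble::tibble(
    id = igraph::vertex_attr(g, "name"),
    type = igraph::vertex_attr(g, "type"),
    direction = igraph::vertex_attr(g, "direction")
  )
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(from = el[, 1], to = el[, 2],
                          type = igraph::edge_attr(g, "type"))
  regulatory_network(nodes, edges)
}
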