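#' Identify risk genes: core genes that are differentially expressed
#'
#' A risk gene is a leading-edge (core) gene of a risk pathway that is also
#' a called DEG; the risk set is the exact intersection, annotated with DE
#' direction and pathway membership.
#'
#' @param core Character vector of core genes (see [core_genes()]).
#' @param degs Called DE gene table (a `de_table`/`meta_de_table` subset)
#'   with columns `feature` and `direction`, or a character vector.
#' @param pathways Optional `gene_set_collection` used to annotate member
#'   pathways.
#' @param risk_pathways Optional restriction of the membership annotation to
#'   these pathway names.
#' @return Tibble of class `risk_gene_set`: `gene`, `direction`, `pathways`
#'   (list-column). Empty (with a warning) if the intersection is empty.
#' @export
identify_risk_genes <- function(core, degs, pathways = NULL,
                                risk_pathways = NULL) {
  if (is.data.frame(degs)) {
    de_ids <- degs$feature
    de_dir <- setNames(degs$direction, degs$feature)
  } else {
    de_ids <- as.character(degs)
    de_dir <- setNames(rep(NA_character_, length(de_ids)), de_ids)
  }
  risk <- sort(intersect(core, de_ids))
  if (!length(risk)) {
    warning("no risk genes: core genes and DEGs are disjoint", call. = FALSE)
  }
  member <- rep(list(character()), length(risk))
  if (!is.null(pathways)) {
    sets <- as.list(pathways)
    if (!is.null(risk_pathways)) sets <- sets[intersect(risk_pathways, names(sets))]
    member <- lapply(risk, function(g) {
      names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
    })
  }
  out <- tibble::tibble(gene = risk,
                        direction = unname(de_dir[risk]),
                        pathways = member)
  structure(out, class = c("risk_gene_set", class(out)))
}

#' Assemble miRNA-gene-pathway triples
#'
#' Emits every (miRNA, gene, pathway) triple in which the miRNA is a DEmiR,
#' the gene is a risk gene targeted by that miRNA, and the gene belongs to
#' that risk pathway. Each triple is labeled with both directions and their
#' concordance: `opposite` (the canonically repressive pattern) when the
#' miRNA and its target change in different directions, `same` otherwise.
#'
#' @param demirs Called DE miRNA table with columns `feature` (or `mirna`)
#'   and `direction`.
#' @param risk_genes A `risk_gene_set` from [identify_risk_genes()].
#' @param risk_pathways Character vector of risk pathway names or a
#'   `sig_pathway_set`.
#' @param targets A `target_map`.
#' @param pathways A `gene_set_collection`.
#' @return Tibble of class `triple_set`: `mirna`, `gene`, `pathway`,
#'   `mirna_direction`, `gene_direction`, `concordance`.
#' @export
build_triples <- function(demirs, risk_genes, risk_pathways, targets,
                          pathways) {
  if (is.data.frame(risk_pathways)) {
    risk_pathways <- risk_pathways$pathway[risk_pathways$risk]
  }
  if (is.data.frame(demirs)) {
    ids <- if ("mirna" %in% names(demirs)) demirs$mirna else demirs$feature
    mir_tbl <- tibble::tibble(mirna = ids, mirna_direction = demirs$direction)
  } else {
    mir_tbl <- tibble::tibble(mirna = as.character(demirs),
                              mirna_direction = NA_character_)
  }
  gene_tbl <- tibble::tibble(gene = risk_genes$gene,
                             gene_direction = risk_genes$direction)
  membership <- purrr::imap_dfr(
    as.list(pathways)[intersect(risk_pathways, names(pathways))],
    function(s, nm) tibble::tibble(pathway = nm, gene = s)
  )
  out <- tibble::as_tibble(targets) |>
    dplyr::inner_join(mir_tbl, by = "mirna") |>
    dplyr::inner_join(gene_tbl, by = "gene") |>
    dplyr::inner_join(membership, by = "gene",
                      relationship = "many-to-many") |>
    dplyr::mutate(concordance = ifelse(
      .data$mirna_direction == .data$gene_direction, "same", "opposite"
    )) |>
    dplyr::select("mirna", "gene", "pathway", "mirna_direction",
                  "gene_direction", "concordance") |>
    dplyr::distinct() |>
    dplyr::arrange(.data$mirna, .data$gene, .data$pathway)
  structure(out, class = c("triple_set", class(out)))
}

#' Construct a regulatory network
#'
#' @param nodes Tibble with columns `id`, `type` (`miRNA`/`gene`/`pathway`),
#'   `direction`.
#' @param edges Tibble with columns `from`, `to`, `type`
#'   (`targets`/`member_of`/`ppi`).
#' @return An object of class `regulatory_network`.
#' @export
regulatory_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "type", "direction") %in% names(nodes)),
            all(c("from", "to", "type") %in% names(edges)))
  stopifnot(!anyDuplicated(nodes$id),
            all(nodes$type %in% c("miRNA", "gene", "pathway")),
            all(edges$type %in% c("targets", "member_of", "ppi")),
            all(c(edges$from, edges$to) %in% nodes$id))
  ntype <- setNames(nodes$type, nodes$id)
  ok <- (edges$type == "targets" & ntype[edges$from] == "miRNA" &
           ntype[edges$to] == "gene") |
    (edges$type == "member_of" & ntype[edges$from] == "gene" &
       ntype[edges$to] == "pathway") |
    (edges$type == "ppi" & ntype[edges$from] == "gene" &
       ntype[edges$to] == "gene")
  if (!all(ok)) stop("edge endpoints violate type constraints", call. = FALSE)
  key <- ifelse(edges$type == "ppi",
                paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
                      edges$type),
                paste(edges$from, edges$to, edges$type))
  edges <- edges[!duplicated(key), , drop = FALSE]
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf(
    "<regulatory_network> %d nodes (%d miRNA, %d gene, %d pathway); %d edges (%d targets, %d member_of, %d ppi)\n",
    nrow(x$nodes), sum(x$nodes$type == "miRNA"), sum(x$nodes$type == "gene"),
    sum(x$nodes$type == "pathway"), nrow(x$edges),
    sum(x$edges$type == "targets"), sum(x$edges$type == "member_of"),
    sum(x$edges$type == "ppi")
  ))
  invisible(x)
}

#' Build the tripartite regulatory network with PPI overlay
#'
#' Nodes and `targets`/`member_of` edges come from the triples; `ppi` edges
#' are added only where both endpoints are risk genes appearing in at least
#' one triple.
#'
#' @param triples A `triple_set` from [build_triples()].
#' @param ppi Optional `ppi_network` to overlay.
#' @return A `regulatory_network`.
#' @export
build_network <- function(triples, ppi = NULL) {
  mirs <- unique(triples[, c("mirna", "mirna_direction")])
  genes <- unique(triples[, c("gene", "gene_direction")])
  paths <- unique(triples$pathway)
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = mirs$mirna, type = "miRNA",
                   direction = mirs$mirna_direction),
    tibble::tibble(id = genes$gene, type = "gene",
                   direction = genes$gene_direction),
    tibble::tibble(id = paths, type = "pathway", direction = NA_character_)
  )
  edges <- dplyr::bind_rows(
    tibble::tibble(from = triples$mirna, to = triples$gene, type = "targets"),
    tibble::tibble(from = triples$gene, to = triples$pathway,
                   type = "member_of")
  ) |> dplyr::distinct()
  if (!is.null(ppi) && nrow(ppi) && nrow(genes)) {
    keep <- ppi$a %in% genes$gene & ppi$b %in% genes$gene
    if (any(keep)) {
      edges <- dplyr::bind_rows(
        edges,
        tibble::tibble(from = ppi$a[keep], to = ppi$b[keep], type = "ppi")
      )
    }
  }
  regulatory_network(nodes, edges)
}

#' Convert package graph objects to igraph
#'
#' @param x A `regulatory_network` or `ppi_network`.
#' @return An undirected simple igraph graph with `type`/`direction` node
#'   attributes and `type` edge attribute where available.
#' @export
as_igraph <- function(x) {
  if (inherits(x, "regulatory_network")) {
    g <- igraph::graph_from_data_frame(
      x$edges, directed = FALSE,
      vertices = data.frame(name = x$nodes$id, type = x$nodes$type,
                            direction = ifelse(is.na(x$nodes$direction),
                                               "none", x$nodes$direction))
    )
  } else if (inherits(x, "ppi_network")) {
    g <- igraph::graph_from_data_frame(as.data.frame(x)[, c("a", "b")],
                                       directed = FALSE)
  } else if (inherits(x, "igraph")) {
    g <- x
  } else {
    stop("cannot convert to igraph", call. = FALSE)
  }
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Node topology metrics
#'
#' Treats the graph as one undirected simple graph and reports, per node:
#' degree; unnormalized betweenness centrality (each unordered pair counted
#' once); closeness `(n_reachable - 1) / sum(d)` over the node's component;
#' local clustering coefficient `2 * triangles / (k * (k - 1))` (0 for
#' degree < 2); average shortest path length to reachable nodes; and the
#' topological coefficient: the mean over partner nodes `u` sharing at
#' least one neighbor of `(shared_neighbors(v, u) + [u adjacent to v]) /
#' degree(v)`, 0 for degree < 2.
#'
#' @param net A `regulatory_network`, `ppi_network` or igraph graph.
#' @return Tibble (class `node_topology`) ordered by decreasing degree:
#'   `node`, `degree`, `betweenness`, `closeness`, `clustering`,
#'   `avg_shortest_path`, `topological_coefficient` (plus `type` for
#'   regulatory networks).
#' @export
node_topology <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0) {
    return(structure(
      tibble::tibble(node = character(), degree = integer(),
                     betweenness = numeric(), closeness = numeric(),
                     clustering = numeric(), avg_shortest_path = numeric(),
                     topological_coefficient = numeric()),
      class = c("node_topology", "tbl_df", "tbl", "data.frame")
    ))
  }
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  D <- igraph::distances(g)
  diag(D) <- Inf
  reach <- is.finite(D)
  n_reach <- rowSums(reach)
  sum_d <- rowSums(ifelse(reach, D, 0))
  clo <- ifelse(n_reach > 0, n_reach / sum_d, 0)
  aspl <- ifelse(n_reach > 0, sum_d / n_reach, 0)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")

  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  S <- A %*% A  # shared-neighbor counts
  J <- S + A
  tc <- vapply(seq_len(n), function(v) {
    if (deg[v] < 2) return(0)
    partners <- which(S[v, ] >= 1)
    partners <- setdiff(partners, v)
    if (!length(partners)) return(0)
    mean(J[v, partners]) / deg[v]
  }, numeric(1))

  out <- tibble::tibble(
    node = igraph::V(g)$name,
    degree = as.integer(deg),
    betweenness = unname(btw),
    closeness = unname(clo),
    clustering = unname(cc),
    avg_shortest_path = unname(aspl),
    topological_coefficient = tc
  )
  if (!is.null(igraph::vertex_attr(g, "type"))) {
    out$type <- igraph::V(g)$type
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$degree), .data$node)
  structure(out, class = c("node_topology", class(out)))
}

#' Top hub nodes by degree
#'
#' @param topology A `node_topology` tibble.
#' @param k Number of hubs (default 3). Ties are broken by betweenness,
#'   then node id.
#' @return The top-`k` rows.
#' @export
top_hubs <- function(topology, k = 3) {
  topology |>
    dplyr::arrange(dplyr::desc(.data$degree), dplyr::desc(.data$betweenness),
                   .data$node) |>
    head(k)
}

#' Count opposite- vs same-trend DEmiR-risk gene pairs
#'
#' Deduplicates triples to unique (miRNA, gene) pairs (a pair linked via
#' several pathways counts once) and partitions them by expression-trend
#' concordance.
#'
#' @param triples A `triple_set`.
#' @return A list with elements `opposite`, `same` (counts) and `pairs`
#'   (the deduplicated pair tibble).
#' @export
classify_concordance <- function(triples) {
  pairs <- tibble::as_tibble(triples) |>
    dplyr::distinct(.data$mirna, .data$gene, .keep_all = TRUE) |>
    dplyr::select("mirna", "gene", "mirna_direction", "gene_direction",
                  "concordance")
  list(opposite = sum(pairs$concordance == "opposite"),
       same = sum(pairs$concordance == "same"),
       pairs = pairs)
}
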