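#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `x` successes when `m_draws` genes are
#' drawn without replacement from a background of `n_background` genes of
#' which `k_successes` are targets: the one-sided over-representation test
#' behind every miRNA-pathway pair. Computed in log space for stability.
#'
#' @param x Observed overlap count.
#' @param n_background Background gene count (N).
#' @param k_successes Number of targets of the miRNA in the background (K).
#' @param m_draws Pathway size within the background (M).
#' @return `P(X >= x)`, a probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(x, n_background, k_successes, m_draws) {
  N <- n_background; K <- k_successes; M <- m_draws
  if (any(c(x, N, K, M) < 0) || K > N || M > N || x > min(K, M)) {
    stop("invalid hypergeometric parameters", call. = FALSE)
  }
  if (x == 0) return(1)
  j <- x:min(K, M)
  lt <- lchoose(K, j) + lchoose(N - K, M - j) - lchoose(N, M)
  lt <- lt[is.finite(lt)]
  if (!length(lt)) return(0)
  mx <- max(lt)
  min(1, exp(mx + log(sum(exp(lt - mx)))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: sort the p values ascending, set
#' `adj_(k) = min over j >= k of p_(j) * n / j`, cap at 1, and return the
#' adjusted values in the original order.
#'
#' @param p Vector of p values in (0, 1].
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p values must lie in (0, 1]", call. = FALSE)
  }
  n <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- adj_sorted
  out
}

#' Test DEmiR target over-representation in risk pathways
#'
#' For every (differentially expressed miRNA, risk pathway) combination with
#' at least one target and one pathway gene in the background, computes the
#' upper-tail hypergeometric p value for the overlap between the miRNA's
#' target set and the pathway's gene set, then applies Benjamini-Hochberg
#' adjustment across the whole table. Pairs with adjusted p below
#' `p_threshold` are flagged significant (set `use_adjusted = FALSE` to
#' threshold the raw p instead).
#'
#' @param demirs Character vector of DE miRNA ids, or a tibble with a
#'   `mirna` column (e.g. a called miRNA `de_table` renamed accordingly).
#' @param targets A `target_map`.
#' @param risk_pathways Character vector of risk pathway names, or the
#'   tibble returned by [select_sig_pathways()] (its flagged rows are used).
#' @param pathways A `gene_set_collection`.
#' @param background Character vector: the background gene universe. Genes
#'   outside it are ignored in all counts.
#' @param p_threshold Significance cutoff (default 0.05).
#' @param use_adjusted Threshold adjusted (default) or raw p.
#' @return Tibble of class `mirna_pathway_table` with columns `mirna`,
#'   `pathway`, `x`, `k`, `m`, `n`, `p`, `p_adj`, `significant`; the number
#'   of DEmiRs tested is kept in attribute `n_demirs`.
#' @export
test_mirna_pathways <- function(demirs, targets, risk_pathways, pathways,
                                background, p_threshold = 0.05,
                                use_adjusted = TRUE) {
  if (is.data.frame(demirs)) demirs <- demirs$mirna
  demirs <- unique(as.character(demirs))
  if (is.data.frame(risk_pathways)) {
    risk_pathways <- risk_pathways$pathway[risk_pathways$risk]
  }
  background <- unique(as.character(background))
  if (!length(background)) stop("background must be nonempty", call. = FALSE)
  N <- length(background)

  tmap <- tibble::as_tibble(targets) |>
    dplyr::filter(.data$mirna %in% demirs, .data$gene %in% background)
  target_sets <- split(tmap$gene, tmap$mirna)
  skipped <- setdiff(demirs, names(target_sets))
  if (length(skipped)) {
    message("skipping ", length(skipped),
            " DEmiR(s) with no targets in background")
  }
  path_sets <- lapply(as.list(pathways)[intersect(risk_pathways, names(pathways))],
                      intersect, background)
  path_sets <- path_sets[lengths(path_sets) > 0]

  grid <- tidyr::expand_grid(mirna = names(target_sets),
                             pathway = names(path_sets))
  if (!nrow(grid)) {
    out <- tibble::tibble(mirna = character(), pathway = character(),
                          x = integer(), k = integer(), m = integer(),
                          n = integer(), p = numeric(), p_adj = numeric(),
                          significant = logical())
    return(structure(out, class = c("mirna_pathway_table", class(out)),
                     n_demirs = length(demirs)))
  }
  rows <- purrr::pmap_dfr(grid, function(mirna, pathway) {
    tg <- target_sets[[mirna]]
    pw <- path_sets[[pathway]]
    x <- length(intersect(tg, pw))
    tibble::tibble(mirna = mirna, pathway = pathway,
                   x = x, k = length(tg), m = length(pw), n = N,
                   p = hypergeom_upper_tail(x, N, length(tg), length(pw)))
  })
  rows$p_adj <- bh_adjust(rows$p)
  rows$significant <- if (use_adjusted) rows$p_adj < p_threshold else
    rows$p < p_threshold
  rows <- dplyr::arrange(rows, .data$p_adj, .data$p, .data$mirna, .data$pathway)
  structure(rows, class = c("mirna_pathway_table", class(rows)),
            n_demirs = length(demirs))
}

#' Generic over-representation analysis for a gene list
#'
#' The same upper-tail hypergeometric machinery applied to a single gene
#' list against each set of a collection: the standard functional-enrichment
#' step for, e.g., the targets of the DE miRNAs.
#'
#' @param gene_list Character vector of genes of interest.
#' @param pathways A `gene_set_collection` (or named list).
#' @param background Background gene universe.
#' @param p_threshold Cutoff applied to the raw p (default 0.05), with BH
#'   adjusted p reported alongside.
#' @return Tibble with columns `pathway`, `x`, `k`, `m`, `n`, `p`, `p_adj`,
#'   `significant`.
#' @export
ora_enrich <- function(gene_list, pathways, background, p_threshold = 0.05) {
  background <- unique(as.character(background))
  gl <- intersect(unique(gene_list), background)
  N <- length(background)
  rows <- purrr::imap_dfr(as.list(pathways), function(pw, nm) {
    pw <- intersect(pw, background)
    if (!length(pw)) return(NULL)
    x <- length(intersect(gl, pw))
    tibble::tibble(pathway = nm, x = x, k = length(gl), m = length(pw), n = N,
                   p = hypergeom_upper_tail(x, N, length(gl), length(pw)))
  })
  if (!nrow(rows)) return(rows)
  rows$p_adj <- bh_adjust(rows$p)
  rows$significant <- rows$p < p_threshold
  dplyr::arrange(rows, .data$p)
}
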